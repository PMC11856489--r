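Package: mitodyn
Title: Comparative Analysis of Fungal Mitochondrial Genomes and Intron Dynamics
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of annotated fungal mitochondrial genomes:
    base composition and strand skew statistics, relative synonymous codon
    usage under the mold mitochondrial genetic code (translation table 4),
    per-gene pairwise Kimura two-parameter distances and Nei-Gojobori (1986)
    Ka/Ks estimates, intron insertion-position mapping onto a reference
    species with tolerance clustering into intron position sets (IPSs),
    intron phase and flanking-sequence profiling, gene-order and breakpoint
    comparison, pairwise synteny-block detection, genome-size component
    regressions, and a mitogenome evolution simulator that emits annotated
    GenBank records together with the ground truth used to validate every
    stage. Reads and writes GenBank flat files, FASTA, TSV, PHYLIP and
    newick.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
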