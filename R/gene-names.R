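# Gene-label normalization. Annotation pipelines emit many spellings for the
# same mitochondrial gene (ATP6 / atpase 6 / atp_6; ND1 / nad1; cytb / cob).
# The synonym table is explicit, versioned data shipped with the package.

.GENE_SYNONYMS <- local({
  syn <- list(
    atp6  = c("atp6", "atpase6", "atpsynthasef0subunit6", "atpase subunit6"),
    atp8  = c("atp8", "atpase8", "atpsynthasef0subunit8"),
    atp9  = c("atp9", "atpase9", "atpsynthasef0subunit9", "olic"),
    cob   = c("cob", "cytb", "cob1", "cytochromeb", "apocytochromeb"),
    cox1  = c("cox1", "co1", "coi", "coxi", "cytochromeoxidasesubunit1",
              "cytochromecoxidasesubunit1"),
    cox2  = c("cox2", "co2", "coii", "coxii",
              "cytochromecoxidasesubunit2"),
    cox3  = c("cox3", "co3", "coiii", "coxiii",
              "cytochromecoxidasesubunit3"),
    nad1  = c("nad1", "nd1", "nadh1", "nadhdehydrogenasesubunit1"),
    nad2  = c("nad2", "nd2", "nadh2", "nadhdehydrogenasesubunit2"),
    nad3  = c("nad3", "nd3", "nadh3", "nadhdehydrogenasesubunit3"),
    nad4  = c("nad4", "nd4", "nadh4", "nadhdehydrogenasesubunit4"),
    nad4L = c("nad4l", "nd4l", "nadh4l", "nadhdehydrogenasesubunit4l"),
    nad5  = c("nad5", "nd5", "nadh5", "nadhdehydrogenasesubunit5"),
    nad6  = c("nad6", "nd6", "nadh6", "nadhdehydrogenasesubunit6"),
    rps3  = c("rps3", "var1", "ribosomalproteins3", "rps3like"),
    rnl   = c("rnl", "rrnl", "lsu", "lsurrna", "largesubunitribosomalrna",
              "21srrna", "23srrna", "rrn26"),
    rns   = c("rns", "rrns", "ssu", "ssurrna", "smallsubunitribosomalrna",
              "15srrna", "16srrna", "rrn18")
  )
  out <- stats::setNames(rep(names(syn), lengths(syn)), unlist(syn))
  out
})

#' Normalize a mitochondrial gene label
#'
#' Case, spacing and punctuation are folded, then the label is looked up in
#' the shipped synonym table (`"ATP6"`, `"atpase 6"` -> `"atp6"`; `"ND1"` ->
#' `"nad1"`; `"cytb"` -> `"cob"`). Labels not in the table are returned
#' as `NA`, which callers treat as an unrecognized / un_ORF-like label.
#'
#' @param x character vector of raw labels
#' @return character vector of canonical names, `NA` where unrecognized
#' @export
normalize_gene_name <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  out <- unname(.GENE_SYNONYMS[key])
  out
}
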