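---
title: "Models and methods behind mitodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodyn)
```

mitodyn implements the comparative-mitogenomics workflow used for small
clades of fungi: composition and skew statistics, codon usage, per-gene
evolutionary rates, intron insertion-site dynamics, gene order and
synteny, and genome-size decomposition. This vignette explains the models
actually implemented, the parameters that matter, the numerical choices at
the edges, and what the bundled simulator does and does not emulate.

## Coordinates, genetic code, and annotation model

Internally every coordinate is 0-based half-open; the GenBank reader and
writer convert to 1-based inclusive at the file boundary only. All
translation uses the mold mitochondrial genetic code (NCBI table 4), whose
one relevant difference from the standard code is UGA = tryptophan; stops
are limited to UAA and UAG.

A genome is a `mitogenome`: a sequence plus a typed feature table
(core PCG / tRNA / rRNA / un_ORF / HEG / intron), with exons as ordered
segments. Introns may be annotated explicitly or implied by `join()` gaps
in a CDS; both routes are supported and checked against each other when
both are present, because annotation pipelines differ on this point.
Gene labels are normalized through an explicit synonym table shipped with
the package (`"ND1"`, `"cytb"`, `"atpase 6"` and similar variants), since
no standard exists for mitochondrial gene naming in deposited records.
Records with an origin-wrapping feature are rotated so that nothing wraps;
the rotation offset is retained as an attribute.

## Composition and the component partition

AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C); a zero
denominator yields `NaN` rather than 0, because an absent skew is not a
balanced one. The genome decomposition assigns every position to exactly
one of five exclusive categories with priority core-PCG exon > RNA exon >
intron > un_ORF > intergenic, which makes the five lengths sum to the
genome length by construction — an invariant asserted throughout the test
suite. Homing-endonuclease genes are measured as an *overlay*: a HEG
position stays counted in its host category (almost always intronic).
This resolves cleanly the tension between five-fraction stacked summaries
and six-component correlation analyses: both are served by the same
partition without double counting. rps3 counts as a core PCG even when it
sits inside rnl; the priority rule (core > RNA) settles the overlap.

## Repeat detection

The repeat detectors are deliberately simplified, parameter-explicit
stand-ins for Tandem Repeats Finder and intragenomic BLASTn, and the
package's claims about them are property-based (planted repeats must be
recovered), not score-compatible with those tools.

*Tandem*: for each unit length p (default 10–200), positions matching at
lag p are run-length encoded; exact runs of at least min(p, 12) seed
arrays that are greedily widened while adjacent-copy identity stays at or
above `min_identity` (default 0.8, both locally for the absorbed stretch
and globally). An array spanning run + p nucleotides has (run + p)/p
copies; arrays with ≥ 1.9 copies are reported, so a clean two-copy
duplication passes. Nested re-finds of the same array at multiples of the
unit are dropped, preferring the smallest unit.

*Dispersed and synteny*: exact 12-mer seeding, grouping by diagonal, and
gapless x-drop extension (match +1, mismatch −2, drop 20). Defaults
mirror the reported ranges for intragenomic duplications (≥ 35 nt,
identity ≥ 0.76) and synteny blocks (≥ 500 nt, identity ≥ 0.7). The
engine is gapless by design: a homologous region interrupted by an indel
(an intron gained in one genome, say) is reported as separate blocks,
which is the behaviour wanted for synteny ribbon plots. E-values are
replaced by the two thresholds; this is a documented deviation from
BLASTn. k-mers containing N never seed, and k-mers occurring more than
64 times are skipped as low-complexity.

## Codon usage

RSCU(c) = n(c) · k / Σ n(c′), with the synonymous family and its size k
defined strictly by code 4 — so tryptophan is a two-codon family
{UGA, UGG} and families are never borrowed from the standard code. Stop
codons are excluded from RSCU; single-codon families get RSCU 1 when
observed; a family with zero total is `NaN` (undefined), not 0 and not 1.
Within every family with observations the mean RSCU is exactly 1, an
identity the tests assert to machine precision. Codons containing N are
not counted. Counts include the initiation codon and the terminal stop;
the stop never reaches an RSCU value anyway, and start/stop usage is
reported separately as a per-gene census.

## Alignment

Protein-coding genes are aligned at the amino-acid level by global
Needleman–Wunsch (BLOSUM62, gap open 10, extend 1) and back-mapped to
codons; RNA genes are aligned at the nucleotide level (match 2, mismatch
−3, gap open 5, extend 2). A deterministic in-package aligner was chosen
over an external aligner binary: core-gene alignments at within-genus
divergences are unambiguous, and determinism matters more here than
alignment heuristics. Columns containing a gap or an N are excluded from
distance estimation but retained for coordinate mapping.

## Distances and selection

K2P: d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q) with P and Q the transition and
transversion proportions over compared sites. Log-domain violations
(saturation) yield `NaN` with the offending pair dropped — and counted —
when summarizing medians per gene.

Ka/Ks follows Nei–Gojobori (1986). Synonymous site counts use the classic
per-position fractions; a change that would create a stop codon counts as
nonsynonymous, which keeps S + N exactly 3 × codons (asserted exactly in
tests). Observed differences between codons differing at 2–3 positions
average over all mutational pathways, excluding pathways that pass
through a stop codon; if every pathway is blocked, all are counted, so the
estimate is always defined. Proportions are Jukes–Cantor corrected,
d = −¾ ln(1 − 4p/3), undefined at p ≥ 3/4. The exact algorithm used by
other Ka/Ks software varies and is rarely stated; this package pins its
own definition with an exhaustive pathway-enumeration oracle in the test
suite. The neighbor-joining tree on mean per-gene K2P distances is a
deliberately lightweight summary — Bayesian and maximum-likelihood
phylogenetics are out of scope.

A 14-gene variant (`gene_set = "14"`, dropping rps3) is available because
rps3 is a ribosomal protein often excluded from respiratory-chain gene
analyses.

## Intron position sets

An intron's position is the count of host-gene coding nucleotides 5' of
its insertion point (`local_pos`); its phase is `local_pos mod 3`, with 0
meaning between codons. Positions are mapped onto a configurable
reference species through the codon-aware alignment (nucleotide alignment
for rnl/rns, which also get phase = NA): the reference position is the
number of reference nucleotides aligned strictly 5' of the insertion
point, and an insertion facing a reference gap takes the nearest 5'
reference nucleotide. If the host gene is missing from the reference the
intron is mapped through the first other species carrying the gene and
flagged `indirect`.

Clustering into intron position sets uses single linkage with a maximum
gap of 3 nt between *adjacent* member positions. The published tolerance
rule is stated pairwise ("three position differences are still the same
site"); single linkage is the natural transitive closure, and it means a
chain {100, 103, 106} is one IPS even though its extremes differ by 6.
This is a documented, tested decision — with tolerance 0 the catalog
reduces exactly to distinct (gene, position) pairs, which is the oracle
the tests use. The representative position (and the `gene-pos` id) is the
reference species' own position when present, else the minimum member.
Sharing is reported as the full spectrum of carrier counts
(1..n species), so both "shared by ≥ 2" and "shared by all" readings are
derivable; the package does not hard-code either definition of "common".

Flanking profiles take 15 nt of exonic sequence on each side of the
insertion point (truncated flanks are padded with N and excluded
per-position), giving per-position base frequencies, a majority consensus
with IUPAC codes on ties, and the tally of the introns' own 5'
dinucleotides — group-I-like introns typically begin GT.

## Gene order and breakpoints

The canonical order of the 17 markers is their start-coordinate order on
the linearized circle, rotated to cox1; it is invariant under rotation of
the input by construction and tested. Breakpoint distance counts circular
strand-aware adjacencies of one order absent from the other; 0 iff the
canonical orders coincide. All genes of the emulated genomes lie on one
strand, but adjacency comparison is signed so inversions would register.
The two published Hypocreales arrangements (the shared order and the
Stachybotrys/Metacordyceps order) ship as named constructors; their
breakpoint distance, 3, is verified against a brute-force adjacency
comparison in the tests.

## Size regressions

Ordinary least squares of genome length on each component length, with
R² the squared Pearson correlation and the p-value from
t = r√((n−2)/(1−r²)) on n−2 degrees of freedom — identical to the OLS
slope test for simple regression, which is why the choice between
"Pearson test" and "regression" is immaterial here. Zero variance in
either variable gives an undefined (`NaN`) result rather than 0. The
package asserts the *ordering* property on simulated cohorts (intronic R²
far above RNA-region R² when intron content drives size), not any
particular printed value, since those depend on the specific genomes.

## The simulator: what it emulates, and what it does not

`simulate_mitogenomes()` builds an ancestral genome — 15 core PCGs with
realistic lengths (atp8 147 nt up to nad5 1980 nt), rnl/rns, 26 tRNAs,
8 un_ORFs and AT-rich spacers in the conserved Hypocreales order — and
evolves it along a user tree. Defaults were chosen once to match the
emulated cohort: genomes land at 40–100 kb; root base frequencies
(A 0.38, C 0.12, G 0.15, T 0.35) give GC ≈ 27% in non-coding sequence
(genome-wide GC realizes slightly higher, ≈ 29%, because coding
constraints enrich G+C) with both skews positive; intron lengths are
log-normal with median ≈ 1.4 kb so the length histogram peaks in the
1000–2000 nt bin; 70% of introns ≥ 800 nt carry an embedded
homing-endonuclease ORF; intron gain and loss rates (6 and 1 events per
gene per unit branch length, with 12 ancestral introns) produce per-leaf
intron counts and sharing structure in the range reported for real
congeneric cohorts; half of new insertions snap to codon boundaries,
reflecting the phase-0 excess of group-I intron sites.

Substitution follows the K2P process exactly: per-site events at rate t,
transitions with probability κ/(κ+2). On coding genes, nonsynonymous
changes are accepted with probability ω and stop-creating changes
rejected — a simple rejection-sampling stand-in for codon models that
produces realized Ka/Ks below ω reliably but is not a Goldman–Yang model;
the estimator-recovery tests therefore check sign and calibration
(estimates within a few percent of truth at d = 0.1), not exact ω
recovery. Start and stop codons are frozen under selection. Non-coding
elements (tRNAs, spacers, un_ORFs) also undergo small indels so the RNA
and intergenic fractions vary between leaves as they do in real cohorts;
coding indels (codon-multiple, offset-shifting) are off by default and
exist to exercise alignment-mediated position mapping.

The simulator emits the complete truth — intron event log, per-leaf
component lengths, a site × species presence matrix keyed by ancestral
(gene, offset) — and the package's extractors are required to reproduce
it exactly (decomposition equals the truth table; IPS clustering at
tolerance 0 on indel-free cohorts equals the presence matrix). Two
independent gains at the identical coding offset would merge into one
site in both the truth matrix and the catalog; that is what a
position-based IPS definition measures, and at these rates it is
vanishingly rare.

What passing these tests does *not* show about real data: the simulator
has no tRNA secondary structure, no group I/II intron structure, no
recombination, no rate heterogeneity across sites, and its intergenic
spacers are i.i.d. sequence. Conclusions about detector sensitivity on
real repeat families or about alignment quality at deep divergences do
not follow from it.

## Problem sizes and numerical edges

The test suite and the acceptance script run simulated cohorts of seven
genomes of ~55–62 kb, 50-replicate estimator-recovery experiments at
10 kb sites, and exhaustive oracles on inputs of ≤ 100 units; the full
suite completes in about two minutes on one CPU. Undefined quantities are
uniformly `NaN`-propagated and dropped-with-count in summaries: saturated
K2P pairs, Ks = 0 ratios, empty RSCU families, zero-variance regressions.
Ties in flank consensus become IUPAC codes. Negative NJ branch lengths
are clamped to zero with a warning. The ±3 nt IPS tolerance, the
> 500 bp synteny threshold, genetic code 4, and the reference-species
convention are all defaults of `pipeline_config()` and changeable per
run.

## Known limitations

GenBank parsing covers the feature types this workflow needs (CDS, tRNA,
rRNA, intron, with join/complement and origin wraps) rather than the full
flat-file grammar. The gapless block detector underestimates block counts
between highly diverged genomes (identity near its threshold) because
seeds become sparse. Ka/Ks is NG86 only — no maximum-likelihood dN/dS,
no rate variation. The NJ tree is a summary, not an inference. Repeat
detectors are not scoring-compatible with TRF/BLASTn and should not be
used to reproduce their exact hit lists.
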