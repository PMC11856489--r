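# Deterministic global alignment used for distance estimation and intron
# position mapping. Protein-coding genes are aligned at the amino-acid
# level (Needleman-Wunsch, BLOSUM62, gap open 10 / extend 1) and the
# alignment is back-mapped to codons; RNA genes are aligned at the
# nucleotide level.

#' Codon-aware global alignment of two coding sequences
#'
#' Both CDS are translated under genetic code 4, globally aligned as
#' proteins, and the alignment is mapped back to codons. Columns containing
#' a gap or an N in either codon are excluded from `pairs` (the gap-free
#' codon columns used for K2P and Ka/Ks) but retained in `columns` for
#' coordinate mapping.
#'
#' @param cds_a,cds_b `coding_sequence` objects (see [extract_cds()]) of
#'   the same gene, or plain in-frame nucleotide strings
#' @return object of class `codon_alignment`: `columns` (tibble with
#'   `idx_a`, `idx_b`: 1-based codon index or NA for a gap), `pairs`
#'   (tibble `codon_a`, `codon_b`), plus `gene` and the two ids
#' @export
align_codon_aware <- function(cds_a, cds_b) {
  sa <- cds_nt(cds_a); sb <- cds_nt(cds_b)
  ca <- codon_split(trim_to_frame(sa)); cb <- codon_split(trim_to_frame(sb))
  # strip terminal stop codons so they don't enter the alignment
  if (length(ca) > 0 && ca[length(ca)] %in% .STOP_CODONS) ca <- ca[-length(ca)]
  if (length(cb) > 0 && cb[length(cb)] %in% .STOP_CODONS) cb <- cb[-length(cb)]
  if (length(ca) == 0 || length(cb) == 0) stop("empty coding overlap")
  aa_a <- paste(vapply(ca, aa_of, character(1)), collapse = "")
  aa_b <- paste(vapply(cb, aa_of, character(1)), collapse = "")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_a), Biostrings::AAString(aa_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
    type = "global")
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  idx_a <- ifelse(al_a == "-", NA_integer_, cumsum(al_a != "-"))
  idx_b <- ifelse(al_b == "-", NA_integer_, cumsum(al_b != "-"))
  columns <- tibble::tibble(idx_a = idx_a, idx_b = idx_b)
  ok <- !is.na(idx_a) & !is.na(idx_b)
  pair_a <- ca[idx_a[ok]]; pair_b <- cb[idx_b[ok]]
  clean <- !grepl("N", pair_a, fixed = TRUE) & !grepl("N", pair_b, fixed = TRUE)
  structure(
    list(columns = columns,
         pairs = tibble::tibble(codon_a = pair_a[clean],
                                codon_b = pair_b[clean]),
         codons_a = ca, codons_b = cb,
         gene = cds_gene(cds_a), id_a = cds_id(cds_a), id_b = cds_id(cds_b)),
    class = "codon_alignment"
  )
}

#' Global nucleotide alignment (for rRNA genes)
#'
#' @param seq_a,seq_b nucleotide strings or `coding_sequence` objects
#' @return tibble with `idx_a`, `idx_b` (1-based nucleotide index or NA)
#' @export
align_nucleotide <- function(seq_a, seq_b) {
  sa <- cds_nt(seq_a); sb <- cds_nt(seq_b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb),
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
    type = "global")
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  tibble::tibble(idx_a = ifelse(al_a == "-", NA_integer_, cumsum(al_a != "-")),
                 idx_b = ifelse(al_b == "-", NA_integer_, cumsum(al_b != "-")))
}

#' @noRd
cds_nt <- function(x) {
  if (inherits(x, "coding_sequence")) toupper(x$spliced_seq) else toupper(x)
}

#' @noRd
cds_gene <- function(x) {
  if (inherits(x, "coding_sequence")) x$gene_name else NA_character_
}

#' @noRd
cds_id <- function(x) {
  if (inherits(x, "coding_sequence")) x$species_id else NA_character_
}

#' @noRd
trim_to_frame <- function(s) substr(s, 1, nchar(s) - nchar(s) %% 3)

#' @noRd
aa_of <- function(codon) {
  aa <- .GC4[codon]
  if (is.na(aa) || aa == "*") "X" else unname(aa)
}
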