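#' Count codons over a set of coding sequences
#'
#' Codon counts are aggregated over all supplied CDS of one genome (order
#' invariant). The initiation codon and terminal stop are both counted
#' here; stop codons are excluded later at the [rscu()] step, and start /
#' stop usage is reported by [census_start_stop()]. CDS whose length is
#' not a multiple of 3 are skipped with a warning; codons containing N are
#' not counted.
#'
#' @param cds_set list of `coding_sequence` objects (see [extract_cds()]),
#'   or character vector of in-frame nucleotide sequences
#' @param species_id label attached to the table
#' @return tibble: `species_id`, `codon`, `amino_acid`, `count` (64 rows)
#' @export
count_codons <- function(cds_set, species_id = NULL) {
  seqs <- cds_strings(cds_set)
  if (is.null(species_id)) {
    species_id <- if (inherits(cds_set[[1]], "coding_sequence"))
      cds_set[[1]]$species_id else NA_character_
  }
  counts <- stats::setNames(integer(64), .CODONS)
  for (s in seqs) {
    if (nchar(s) %% 3 != 0) {
      warning("CDS length not a multiple of 3; skipped")
      next
    }
    codons <- codon_split(toupper(s))
    codons <- codons[codons %in% .CODONS]  # drops codons containing N
    tb <- table(codons)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
  }
  tibble::tibble(species_id = species_id, codon = .CODONS,
                 amino_acid = unname(.GC4[.CODONS]),
                 count = unname(counts))
}

#' @noRd
cds_strings <- function(cds_set) {
  if (is.character(cds_set)) return(cds_set)
  if (inherits(cds_set, "coding_sequence")) cds_set <- list(cds_set)
  vapply(cds_set, function(x) {
    if (inherits(x, "coding_sequence")) x$spliced_seq else as.character(x)
  }, character(1))
}

#' Relative synonymous codon usage under genetic code 4
#'
#' RSCU(c) = count(c) * k / sum of counts over the synonymous family of c,
#' where k is the family size under the mold mitochondrial code (TGA codes
#' Trp, so Trp = \{TGA, TGG\} with k = 2). Stop codons are excluded.
#' Families with zero total get `NaN` (undefined); single-codon families
#' get RSCU 1 by convention when observed.
#'
#' @param codon_table output of [count_codons()] (or a compatible tibble
#'   with `codon` and `count`)
#' @return the input with `family_size` and `rscu` columns added, stop
#'   codons removed
#' @export
rscu <- function(codon_table) {
  stopifnot(all(c("codon", "count") %in% names(codon_table)))
  tb <- codon_table[!codon_table$codon %in% .STOP_CODONS, ]
  tb$amino_acid <- unname(.GC4[tb$codon])
  tb$family_size <- as.integer(.FAMILY_SIZE[tb$amino_acid])
  tb |>
    dplyr::group_by(dplyr::across(dplyr::any_of("species_id")),
                    .data$amino_acid) |>
    dplyr::mutate(
      rscu = if (sum(.data$count) == 0) NaN else
        .data$count * .data$family_size / sum(.data$count)) |>
    dplyr::ungroup()
}

#' Start and stop codon census over core protein-coding genes
#'
#' @param cds_set list of `coding_sequence` objects
#' @return tibble: `species_id`, `gene`, `start_codon`, `stop_codon`
#' @export
census_start_stop <- function(cds_set) {
  if (inherits(cds_set, "coding_sequence")) cds_set <- list(cds_set)
  rows <- purrr::map(cds_set, function(x) {
    s <- toupper(x$spliced_seq)
    if (nchar(s) < 6) {
      warning("CDS ", x$gene_name, " shorter than 6 nt; skipped")
      return(NULL)
    }
    tibble::tibble(species_id = x$species_id, gene = x$gene_name,
                   start_codon = substr(s, 1, 3),
                   stop_codon = substr(s, nchar(s) - 2, nchar(s)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(species_id = character(0), gene = character(0),
                          start_codon = character(0), stop_codon = character(0))
  }
  out
}
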