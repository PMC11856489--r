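#' Base composition and strand skews
#'
#' AT skew = (A - T)/(A + T), GC skew = (G - C)/(G + C); GC content is
#' (G + C) over counted A+C+G+T. `N` and other letters are excluded from
#' all ratios. A zero denominator yields `NaN` (undefined), never 0.
#'
#' @param seq nucleotide string, or a [mitogenome()]
#' @return one-row tibble: `a`, `c`, `g`, `t`, `n_other`, `length`,
#'   `gc_content`, `at_skew`, `gc_skew`
#' @export
base_composition <- function(seq) {
  if (is_mitogenome(seq)) seq <- seq$sequence
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) > 0)
  ch <- seq_chars(seq)
  cnt <- table(factor(ch, levels = c(.BASES, "N")))
  a <- cnt[["A"]]; cc <- cnt[["C"]]; g <- cnt[["G"]]; tt <- cnt[["T"]]
  n_other <- length(ch) - (a + cc + g + tt)
  skew <- function(x, y) if (x + y == 0) NaN else (x - y) / (x + y)
  tibble::tibble(
    a = a, c = cc, g = g, t = tt, n_other = n_other, length = length(ch),
    gc_content = if (a + cc + g + tt == 0) NaN else (g + cc) / (a + cc + g + tt),
    at_skew = skew(a, tt),
    gc_skew = skew(g, cc)
  )
}

.COMPONENTS <- c("core_pcg", "rna_region", "intronic", "un_orf", "intergenic")

#' Decompose a genome into exclusive component lengths
#'
#' Every position is assigned to exactly one of five exclusive categories
#' with priority core PCG exon > RNA (rRNA/tRNA) exon > intron > un_ORF >
#' intergenic, so the five lengths always sum to the genome length. Homing
#' endonuclease genes are measured as an *overlay* (`heg` column): HEG
#' positions stay counted in their host category (usually intronic), which
#' supports both five-fraction stacking and six-component correlation
#' without double counting.
#'
#' @param record an annotated [mitogenome()]
#' @return one-row tibble: `species_id`, the five component lengths, `heg`,
#'   `total`, and `prop_*` columns with fractions of total
#' @export
decompose_genome <- function(record) {
  stopifnot(is_mitogenome(record))
  n <- record$length
  # 0 = intergenic, larger codes win
  prio <- c(intergenic = 0L, un_orf = 1L, intronic = 2L, rna_region = 3L,
            core_pcg = 4L)
  lab <- integer(n)  # 0-based positions 0..n-1 -> index 1..n
  feats <- record$features
  cat_map <- c(core_pcg = "core_pcg", trna = "rna_region", rrna = "rna_region",
               intron = "intronic", un_orf = "un_orf")
  # paint in increasing priority so the highest priority wins;
  # ties between two core genes: longer gene painted last (wins)
  ord <- order(prio[cat_map[feats$category]],
               vapply(feats$segments, feature_span_nt, numeric(1)))
  for (i in ord) {
    cat_i <- cat_map[feats$category[i]]
    if (is.na(cat_i)) next  # heg handled as overlay below
    seg <- feats$segments[[i]]
    for (k in seq_len(nrow(seg))) {
      idx <- (seg$start[k] + 1):seg$end[k]
      if (cat_i == "core_pcg" && any(lab[idx] == prio[["core_pcg"]])) {
        warning("overlapping core genes at ", record$id,
                " position ", seg$start[k], "; longer gene takes priority")
      }
      lab[idx] <- prio[[cat_i]]
    }
  }
  heg <- 0L
  hegs <- feats[feats$category == "heg", ]
  if (nrow(hegs) > 0) {
    mask <- logical(n)
    for (i in seq_len(nrow(hegs))) {
      seg <- hegs$segments[[i]]
      for (k in seq_len(nrow(seg))) mask[(seg$start[k] + 1):seg$end[k]] <- TRUE
    }
    heg <- sum(mask)
  }
  lens <- vapply(names(prio), function(nm) sum(lab == prio[[nm]]), integer(1))
  out <- tibble::tibble(
    species_id = record$id,
    core_pcg = lens[["core_pcg"]], rna_region = lens[["rna_region"]],
    intronic = lens[["intronic"]], un_orf = lens[["un_orf"]],
    intergenic = lens[["intergenic"]], heg = heg, total = n
  )
  dplyr::mutate(out, dplyr::across(dplyr::all_of(.COMPONENTS),
                                   ~ .x / n, .names = "prop_{.col}"))
}
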