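#' Extract the spliced coding sequence of a gene
#'
#' Exons are concatenated in transcript order (minus-strand segments are
#' reverse-complemented) and, for protein-coding genes, translated under the
#' mold mitochondrial genetic code (table 4, TGA = Trp). `exon_offsets[i]`
#' is the number of coding nucleotides 5' of intron *i* — the quantity
#' intron insertion positions are expressed in.
#'
#' @param record a [mitogenome()]
#' @param gene canonical gene name (e.g. `"cox1"`, `"rnl"`)
#' @param translate translate to protein? (default: only for core PCGs)
#' @return a list of class `coding_sequence` with elements `gene_name`,
#'   `species_id`, `spliced_seq`, `protein` (or `NA` for RNA genes),
#'   `exon_offsets`, `strand`, `complete` (length divisible by 3) and
#'   `internal_stop` flag
#' @export
extract_cds <- function(record, gene, translate = NULL) {
  stopifnot(is_mitogenome(record))
  feats <- record$features
  hit <- which(feats$gene_name == gene &
                 feats$category %in% c("core_pcg", "rrna", "un_orf", "heg"))
  if (length(hit) == 0) stop("gene ", gene, " not annotated in ", record$id)
  i <- hit[1]
  strand <- feats$strand[i]
  seg <- feats$segments[[i]]

  # if the gene is a single span but explicit introns exist, subtract them
  introns <- feats[feats$category == "intron" & !is.na(feats$parent) &
                     feats$parent == gene, ]
  if (nrow(seg) == 1 && nrow(introns) > 0) {
    ispans <- dplyr::bind_rows(introns$segments) |> dplyr::arrange(.data$start)
    bounds <- c(seg$start, as.vector(rbind(ispans$start, ispans$end)), seg$end)
    m <- matrix(bounds, ncol = 2, byrow = TRUE)
    seg <- tibble::tibble(start = m[, 1], end = m[, 2])
    seg <- seg[seg$end > seg$start, ]
    if (strand == "-") seg <- seg[order(-seg$start), ]
  }

  # transcript order: ascending genomic for +, descending for -
  seg <- if (strand == "+") dplyr::arrange(seg, .data$start) else
    dplyr::arrange(seg, dplyr::desc(.data$start))
  pieces <- purrr::map2_chr(seg$start, seg$end,
                            ~ segment_seq(record$sequence, .x, .y, strand))
  spliced <- paste(pieces, collapse = "")
  lens <- nchar(pieces)
  offsets <- if (length(lens) > 1) cumsum(lens)[-length(lens)] else integer(0)

  is_pcg <- feats$category[i] %in% c("core_pcg", "un_orf", "heg")
  if (is.null(translate)) translate <- is_pcg
  protein <- NA_character_
  internal_stop <- FALSE
  complete <- nchar(spliced) %% 3 == 0
  if (translate) {
    protein <- suppressWarnings(translate_code4(spliced))
    body <- substr(protein, 1, nchar(protein) - 1)
    internal_stop <- grepl("*", body, fixed = TRUE)
    if (!complete) {
      warning("gene ", gene, " in ", record$id,
              ": spliced length not divisible by 3")
    }
  }

  structure(
    list(gene_name = gene, species_id = record$id, spliced_seq = spliced,
         protein = protein, exon_offsets = as.integer(offsets),
         strand = strand, complete = complete, internal_stop = internal_stop),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s [%s], %d nt spliced, %d intron(s)\n",
              x$gene_name, x$species_id, nchar(x$spliced_seq),
              length(x$exon_offsets)))
  invisible(x)
}

#' Find open reading frames on both strands
#'
#' Maximal ORFs under genetic code 4: start codons ATG/TTG/GTG/TTA, stop
#' codons TAA/TAG (TGA codes tryptophan and does not terminate). An ORF is
#' maximal when it uses the first available start after the previous
#' in-frame stop. ORFs overlapping an annotated gene by more than half of
#' their own length are dropped.
#'
#' @param record a [mitogenome()]
#' @param min_aa minimum protein length in amino acids (stop excluded)
#' @return tibble with columns `start`, `end` (0-based half-open, genomic),
#'   `strand`, `length_aa`
#' @export
find_orfs <- function(record, min_aa = 100) {
  stopifnot(is_mitogenome(record), min_aa >= 1)
  n <- record$length
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") record$sequence else revcomp(record$sequence)
    for (frame in 0:2) {
      sub <- substr(s, frame + 1, n)
      codons <- codon_split(sub)
      if (length(codons) == 0) next
      starts <- codons %in% c("ATG", "TTG", "GTG", "TTA")
      stops <- codons %in% .STOP_CODONS
      prev_stop <- 0L
      i <- 1L
      while (i <= length(codons)) {
        if (stops[i]) {
          prev_stop <- i
        } else if (starts[i] && i > prev_stop) {
          # first start since last stop: run to the next stop
          nxt <- which(stops & seq_along(stops) > i)
          if (length(nxt) > 0) {
            j <- nxt[1]
            len_aa <- j - i  # codons from start up to (excl.) stop
            if (len_aa >= min_aa) {
              a <- frame + (i - 1L) * 3L          # 0-based on strand s
              b <- frame + j * 3L                 # includes stop codon
              hits[[length(hits) + 1]] <- tibble::tibble(
                start = if (strand == "+") a else n - b,
                end = if (strand == "+") b else n - a,
                strand = strand, length_aa = len_aa
              )
            }
            prev_stop <- j
            i <- j
          } else {
            break
          }
        }
        i <- i + 1L
      }
    }
  }
  orfs <- if (length(hits) > 0) dplyr::bind_rows(hits) else
    tibble::tibble(start = integer(0), end = integer(0),
                   strand = character(0), length_aa = integer(0))
  if (nrow(orfs) == 0 || nrow(record$features) == 0) {
    return(dplyr::arrange(orfs, .data$start))
  }
  # drop ORFs overlapping annotated genes by > 50% of the ORF length
  gene_feats <- record$features[record$features$category != "intron", ]
  gene_spans <- dplyr::bind_rows(gene_feats$segments)
  keep <- vapply(seq_len(nrow(orfs)), function(i) {
    ov <- pmin(orfs$end[i], gene_spans$end) - pmax(orfs$start[i], gene_spans$start)
    sum(pmax(ov, 0)) <= 0.5 * (orfs$end[i] - orfs$start[i])
  }, logical(1))
  dplyr::arrange(orfs[keep, ], .data$start)
}
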