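#' Annotated mitochondrial genome records
#'
#' A `mitogenome` is a plain S3 list holding one circular (or linear)
#' annotated genome: the nucleotide sequence plus an ordered feature table.
#' Coordinates are 0-based half-open internally; the GenBank reader/writer
#' convert to and from 1-based inclusive at the file boundary.
#'
#' @param id accession or label
#' @param sequence nucleotide string over A,C,G,T,N (uppercased on input)
#' @param features a tibble with columns `category` (one of `core_pcg`,
#'   `trna`, `rrna`, `un_orf`, `heg`, `intron`), `gene_name`, `strand`
#'   (`"+"`/`"-"`), `parent` (gene label for introns/HEGs, else `NA`) and a
#'   list-column `segments` of tibbles with integer columns `start`, `end`
#'   (0-based half-open, ordered 5'->3' in transcript direction)
#' @param organism free-text organism name
#' @param topology `"circular"` or `"linear"`
#' @return an object of class `mitogenome`
#' @export
mitogenome <- function(id, sequence, features = empty_features(),
                       organism = id, topology = "circular") {
  sequence <- toupper(sequence)
  stopifnot(nchar(sequence) > 0)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside A,C,G,T,N")
  }
  topology <- match.arg(topology, c("circular", "linear"))
  features <- validate_features(features, nchar(sequence))
  structure(
    list(id = id, organism = organism, topology = topology,
         sequence = sequence, features = features,
         length = nchar(sequence)),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s (%s), %s, %d bp, %d features\n",
              x$id, x$organism, x$topology, x$length, nrow(x$features)))
  if (nrow(x$features) > 0) {
    print(dplyr::count(x$features, .data$category))
  }
  invisible(x)
}

#' @rdname mitogenome
#' @export
is_mitogenome <- function(x) inherits(x, "mitogenome")

#' @noRd
empty_features <- function() {
  tibble::tibble(
    category = character(0), gene_name = character(0),
    strand = character(0), parent = character(0),
    segments = list()
  )
}

.FEATURE_CATEGORIES <- c("core_pcg", "trna", "rrna", "un_orf", "heg", "intron")

.CORE_PCGS <- c("atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
                "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
                "rps3")

.RRNAS <- c("rnl", "rns")

#' The 17 gene-order markers: 15 core protein-coding genes plus both rRNAs
#' @export
core_markers <- function() c(.CORE_PCGS, .RRNAS)

#' @noRd
validate_features <- function(features, genome_len) {
  features <- tibble::as_tibble(features)
  if (!"parent" %in% names(features)) features$parent <- NA_character_
  need <- c("category", "gene_name", "strand", "parent", "segments")
  missing <- setdiff(need, names(features))
  if (length(missing) > 0) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(features$category), .FEATURE_CATEGORIES)
  if (length(bad) > 0) stop("unknown feature category: ", bad[1])
  for (i in seq_len(nrow(features))) {
    seg <- features$segments[[i]]
    if (nrow(seg) == 0) stop("feature ", features$gene_name[i], ": no segments")
    if (any(seg$start < 0 | seg$end > genome_len | seg$start >= seg$end)) {
      stop("feature ", features$gene_name[i],
           ": segment outside [0, genome length) or empty")
    }
  }
  features[, need]
}

#' Total genomic footprint of a feature (sum of segment lengths)
#' @noRd
feature_span_nt <- function(segments) sum(segments$end - segments$start)

#' First genomic coordinate of a feature (minimum segment start)
#' @noRd
feature_start <- function(segments) min(segments$start)

#' Rotate a circular genome so that position `offset` becomes position 0
#'
#' All feature coordinates are shifted accordingly. Used to linearize
#' records so no feature wraps the origin.
#'
#' @param record a [mitogenome()]
#' @param offset 0-based position of the new origin
#' @return rotated `mitogenome` (with attribute `rotation_offset`)
#' @export
rotate_genome <- function(record, offset) {
  stopifnot(is_mitogenome(record))
  n <- record$length
  offset <- ((offset %% n) + n) %% n
  if (offset == 0) return(record)
  seq2 <- paste0(substr(record$sequence, offset + 1, n),
                 substr(record$sequence, 1, offset))
  feats <- record$features
  feats$segments <- purrr::map(feats$segments, function(seg) {
    seg$start <- (seg$start - offset) %% n
    seg$end <- ((seg$end - 1 - offset) %% n) + 1
    seg
  })
  out <- mitogenome(record$id, seq2, feats, record$organism, record$topology)
  attr(out, "rotation_offset") <- offset
  out
}

#' Subsequence accessor honouring strand
#' @noRd
segment_seq <- function(sequence, start, end, strand = "+") {
  s <- substr(sequence, start + 1, end)
  if (strand == "-") revcomp(s) else s
}
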