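# Gene-order extraction and comparison over the 17 canonical markers
# (15 core protein-coding genes + rnl + rns) of a circular mitogenome.

#' Extract the canonical gene order of a genome
#'
#' The 17 markers are sorted by start coordinate on the linearized circle
#' and rotated so the order starts at cox1. When rps3 is annotated inside
#' rnl the ordering is resolved by rps3's own start coordinate.
#'
#' @param record an annotated [mitogenome()]
#' @return object of class `gene_order`: tibble `marker`, `strand` in
#'   canonical rotation, with `species_id` attribute
#' @export
extract_order <- function(record) {
  stopifnot(is_mitogenome(record))
  feats <- record$features
  mk <- feats[feats$gene_name %in% core_markers() &
                feats$category %in% c("core_pcg", "rrna"), ]
  missing <- setdiff(core_markers(), mk$gene_name)
  if (length(missing) > 0) {
    stop(record$id, ": markers missing from annotation: ",
         paste(missing, collapse = ", "))
  }
  mk <- mk[!duplicated(mk$gene_name), ]
  starts <- vapply(mk$segments, feature_start, numeric(1))
  ord <- order(starts)
  markers <- mk$gene_name[ord]
  strands <- mk$strand[ord]
  at <- which(markers == "cox1")
  rot <- c(at:length(markers), seq_len(at - 1))[seq_along(markers)]
  if (at == 1) rot <- seq_along(markers)
  out <- tibble::tibble(marker = markers[rot], strand = strands[rot])
  structure(out, species_id = record$id, class = c("gene_order", class(out)))
}

#' Construct a gene order from a marker vector (e.g. a published order)
#' @param markers character vector of the 17 markers in circular order
#' @param strands strand per marker (default all `+`)
#' @param species_id label
#' @return a `gene_order`
#' @export
gene_order <- function(markers, strands = rep("+", length(markers)),
                       species_id = NA_character_) {
  stopifnot(setequal(markers, core_markers()),
            length(markers) == length(core_markers()))
  at <- which(markers == "cox1")
  rot <- c(at:length(markers), seq_len(at - 1))
  if (at == 1) rot <- seq_along(markers)
  out <- tibble::tibble(marker = markers[rot], strand = strands[rot])
  structure(out, species_id = species_id,
            class = c("gene_order", class(out)))
}

#' Circular signed adjacencies of a gene order
#' @noRd
order_adjacencies <- function(ord) {
  m <- ord$marker; s <- ord$strand
  nxt <- c(seq_along(m)[-1], 1L)
  # strand-aware unordered pairs: a signed adjacency survives reading the
  # circle in either direction
  vapply(seq_along(m), function(i) {
    a <- paste0(s[i], m[i]); b <- paste0(s[nxt[i]], m[nxt[i]])
    flip <- function(x) chartr("+-", "-+", substr(x, 1, 1)) |>
      paste0(substr(x, 2, nchar(x)))
    key1 <- paste(a, b); key2 <- paste(flip(b), flip(a))
    min(key1, key2)
  }, character(1))
}

#' Breakpoint distance between two circular gene orders
#'
#' The number of (strand-aware) circular adjacencies of `a` that are absent
#' in `b`. Zero iff the canonical orders (and strands) are identical.
#'
#' @param a,b `gene_order` objects over the same marker set
#' @return integer count
#' @export
breakpoint_distance <- function(a, b) {
  stopifnot(setequal(a$marker, b$marker))
  sum(!order_adjacencies(a) %in% order_adjacencies(b))
}

#' Partition gene orders into identical-arrangement classes
#'
#' @param orders list of `gene_order` objects
#' @return tibble: `species_id`, `class` (1-based class index by first
#'   appearance), `order_string`
#' @export
group_arrangements <- function(orders) {
  stopifnot(length(orders) >= 1)
  key <- vapply(orders, function(o) {
    paste(paste0(o$strand, o$marker), collapse = " ")
  }, character(1))
  ids <- vapply(orders, function(o) attr(o, "species_id"), character(1))
  cls <- match(key, unique(key))
  tibble::tibble(species_id = ids, class = cls, order_string = key)
}

#' The gene order shared across most Hypocreales mitogenomes
#' @return a `gene_order`
#' @export
hypocreales_order <- function() {
  gene_order(c("cox1", "nad1", "nad4", "atp8", "atp6", "rns", "cox3",
               "nad6", "rnl", "rps3", "nad2", "nad3", "atp9", "cox2",
               "nad4L", "nad5", "cob"),
             species_id = "hypocreales_shared")
}

#' The divergent order reported for Stachybotrys / Metacordyceps
#' @return a `gene_order`
#' @export
stachybotrys_order <- function() {
  gene_order(c("cox1", "nad2", "nad3", "atp9", "cox2", "nad4L", "nad5",
               "cob", "nad1", "nad4", "atp8", "atp6", "rns", "cox3",
               "nad6", "rnl", "rps3"),
             species_id = "stachybotrys_like")
}

#' Pairwise synteny blocks between two genomes
#'
#' Exact 12-mer seeding with gapless x-drop extension on both orientations,
#' greedy containment dedupe; blocks shorter than `min_len` or below
#' `min_identity` are dropped. Inverted orientation is reported when the
#' minus-strand match wins. Thresholds replace BLASTn e-value statistics.
#'
#' @param rec_a,rec_b [mitogenome()] records (or nucleotide strings)
#' @param min_len minimum block length (nt), default 500
#' @param min_identity minimum identity, default 0.7
#' @return tibble: `id_a`, `id_b`, `start_a`, `end_a`, `start_b`, `end_b`
#'   (0-based half-open), `length`, `identity`, `orientation`
#' @export
find_blocks <- function(rec_a, rec_b, min_len = 500, min_identity = 0.7) {
  sa <- if (is_mitogenome(rec_a)) rec_a$sequence else rec_a
  sb <- if (is_mitogenome(rec_b)) rec_b$sequence else rec_b
  id_a <- if (is_mitogenome(rec_a)) rec_a$id else "a"
  id_b <- if (is_mitogenome(rec_b)) rec_b$id else "b"
  ca <- seq_chars(sa); cb <- seq_chars(sb)
  nb <- length(cb)
  fwd <- gapless_hits(ca, cb, k = 12, min_len, min_identity)
  fwd$orientation <- rep("same", nrow(fwd))
  rev <- gapless_hits(ca, seq_chars(revcomp(sb)), k = 12, min_len,
                      min_identity)
  if (nrow(rev) > 0) {
    sb2 <- nb - rev$end_b + 1L
    eb2 <- nb - rev$start_b + 1L
    rev$start_b <- sb2; rev$end_b <- eb2
  }
  rev$orientation <- rep("inverted", nrow(rev))
  out <- dedupe_hits(dplyr::bind_rows(fwd, rev))
  out$start_a <- out$start_a - 1L
  out$start_b <- out$start_b - 1L
  out <- dplyr::arrange(out, .data$start_a)
  dplyr::bind_cols(tibble::tibble(id_a = rep(id_a, nrow(out)),
                                  id_b = rep(id_b, nrow(out))), out)
}
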