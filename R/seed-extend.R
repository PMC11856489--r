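# Exact k-mer seeding with gapless x-drop extension. This is the shared
# engine behind dispersed-repeat detection (genome vs itself) and pairwise
# synteny-block detection. Deliberately gapless: blocks interrupted by
# indels are reported as separate hits.

#' @noRd
kmer_positions <- function(chars, k) {
  n <- length(chars)
  if (n < k) return(character(0))
  s <- paste(chars, collapse = "")
  substring(s, 1:(n - k + 1), k:n)
}

# Gapless hits between two character vectors on the forward orientation.
# Returns 1-based inclusive spans in each sequence.
#' @noRd
gapless_hits <- function(ca, cb, k, min_len, min_identity,
                         exclude_self_diagonal = FALSE,
                         xdrop = 20, max_kmer_hits = 64) {
  na <- length(ca); nb <- length(cb)
  ka <- kmer_positions(ca, k); kb <- kmer_positions(cb, k)
  if (length(ka) == 0 || length(kb) == 0) return(empty_hits())
  drop_n <- function(x) !grepl("N", x, fixed = TRUE)
  pa <- which(drop_n(ka)); pb <- which(drop_n(kb))
  f <- factor(kb[pb])
  bl <- split(pb, f)
  bl <- bl[lengths(bl) <= max_kmer_hits]
  m <- match(ka[pa], names(bl))
  hit_a <- pa[!is.na(m)]
  if (length(hit_a) == 0) return(empty_hits())
  hit_lists <- bl[m[!is.na(m)]]
  seeds_a <- rep(hit_a, lengths(hit_lists))
  seeds_b <- unlist(hit_lists, use.names = FALSE)
  diag <- seeds_b - seeds_a
  if (exclude_self_diagonal) {
    keep <- diag > 0  # self-comparison: keep one of each symmetric pair
    seeds_a <- seeds_a[keep]; seeds_b <- seeds_b[keep]; diag <- diag[keep]
  }
  if (length(seeds_a) == 0) return(empty_hits())

  out <- list()
  margin <- 2000L  # extension can run past the outermost seeds by at most
                   # ~xdrop mismatches worth of sequence; a generous margin covers that
  for (d in unique(diag)) {
    sa <- sort(unique(seeds_a[diag == d]))
    lo <- max(1L, 1L - d, min(sa) - margin)
    hi <- min(na, nb - d, max(sa) + k - 1L + margin)
    if (hi - lo + 1L < min_len) next
    mv <- ca[lo:hi] == cb[(lo:hi) + d]
    segs <- extend_on_diagonal(mv, sa - lo + 1L, k, xdrop)
    for (r in seq_len(nrow(segs))) {
      len <- segs$hi[r] - segs$lo[r] + 1L
      ident <- mean(mv[segs$lo[r]:segs$hi[r]])
      if (len >= min_len && ident >= min_identity) {
        a1 <- segs$lo[r] + lo - 1L
        out[[length(out) + 1]] <- tibble::tibble(
          start_a = a1, end_a = a1 + len - 1L,
          start_b = a1 + d, end_b = a1 + d + len - 1L,
          length = len, identity = ident
        )
      }
    }
  }
  if (length(out) == 0) return(empty_hits())
  dplyr::distinct(dplyr::bind_rows(out))
}

#' @noRd
empty_hits <- function() {
  tibble::tibble(start_a = integer(0), end_a = integer(0),
                 start_b = integer(0), end_b = integer(0),
                 length = integer(0), identity = numeric(0))
}

# Cluster seed starts on one diagonal and x-drop extend each cluster.
# mv: logical match vector for the diagonal; seed_starts: 1-based indexes
# into mv where a k-long exact match begins.
#' @noRd
extend_on_diagonal <- function(mv, seed_starts, k, xdrop,
                               cluster_gap = 100L) {
  n <- length(mv)
  seed_starts <- seed_starts[seed_starts >= 1 & seed_starts + k - 1 <= n]
  if (length(seed_starts) == 0) {
    return(tibble::tibble(lo = integer(0), hi = integer(0)))
  }
  grp <- cumsum(c(TRUE, diff(seed_starts) > cluster_gap))
  lo <- unname(tapply(seed_starts, grp, min))
  hi <- unname(tapply(seed_starts, grp, max)) + k - 1L
  res <- list()
  for (g in seq_along(lo)) {
    l <- xdrop_extend(mv, hi[g], n, xdrop, dir = 1L)
    r <- xdrop_extend(mv, lo[g], 1L, xdrop, dir = -1L)
    res[[g]] <- c(r, l)
  }
  segs <- unique(do.call(rbind, res))
  tibble::tibble(lo = segs[, 1], hi = segs[, 2])
}

# Extend from `from` toward `limit`; returns the furthest position whose
# prefix score (match +1, mismatch -2) is maximal before dropping `xdrop`
# below the running maximum. Scanned in chunks so that extensions that
# terminate early never touch the rest of the diagonal.
#' @noRd
xdrop_extend <- function(mv, from, limit, xdrop, dir, chunk = 4096L) {
  best_pos <- from; best_sc <- -Inf
  carry_sc <- 0; carry_max <- 0
  pos <- from
  repeat {
    hi <- if (dir > 0) min(limit, pos + chunk - 1L) else
      max(limit, pos - chunk + 1L)
    idx <- seq(pos, hi, by = dir)
    v <- cumsum(3L * mv[idx] - 2L) + carry_sc
    rm <- cummax(pmax(v, carry_max))
    stop_at <- which(rm - v > xdrop)[1]
    upto <- if (is.na(stop_at)) length(idx) else stop_at - 1L
    if (upto > 0) {
      wb <- which.max(v[seq_len(upto)])
      if (v[wb] > best_sc) { best_sc <- v[wb]; best_pos <- idx[wb] }
    }
    if (!is.na(stop_at) || hi == limit) break
    carry_sc <- v[length(v)]; carry_max <- rm[length(rm)]
    pos <- hi + dir
  }
  best_pos
}

# Merge hits contained in (or heavily overlapped by) a longer accepted hit.
#' @noRd
dedupe_hits <- function(hits, frac = 0.5) {
  if (nrow(hits) <= 1) return(hits)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$length))
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    acc <- which(keep[1:(i - 1)])
    ov_a <- pmin(hits$end_a[i], hits$end_a[acc]) -
      pmax(hits$start_a[i], hits$start_a[acc]) + 1
    ov_b <- pmin(hits$end_b[i], hits$end_b[acc]) -
      pmax(hits$start_b[i], hits$start_b[acc]) + 1
    if (any(ov_a > frac * hits$length[i] & ov_b > frac * hits$length[i])) {
      keep[i] <- FALSE
    }
  }
  hits[keep, ]
}
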