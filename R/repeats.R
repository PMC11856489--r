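#' Find tandem repeats by period autocorrelation
#'
#' For each candidate unit length *p*, positions where the sequence matches
#' itself at lag *p* are computed; exact match runs seed candidate arrays
#' that are greedily widened while adjacent-copy identity stays at or above
#' `min_identity`. An array whose match segment spans `run` positions
#' covers `run + p` nucleotides, i.e. `(run + p)/p` copies. Arrays nested
#' inside a longer accepted array (e.g. the same repeat re-found at twice
#' the unit) are dropped.
#' A simplified stand-in for Tandem Repeats Finder with explicit,
#' documented thresholds.
#'
#' @param seq nucleotide string or [mitogenome()]
#' @param min_unit,max_unit unit-length bounds in nt
#' @param min_copies minimum copy number (default 1.9, so near-perfect
#'   two-copy arrays are reported)
#' @param min_identity minimum adjacent-copy identity
#' @return tibble: `start`, `end` (0-based half-open), `unit_length`,
#'   `copy_number`, `identity`, `total_length`, `unit_seq`
#' @export
find_tandem_repeats <- function(seq, min_unit = 10, max_unit = 200,
                                min_copies = 1.9, min_identity = 0.8) {
  if (is_mitogenome(seq)) seq <- seq$sequence
  stopifnot(min_unit >= 1, min_unit <= max_unit, max_unit <= 500)
  ch <- seq_chars(seq)
  n <- length(ch)
  hits <- list()
  for (p in seq(min_unit, min(max_unit, floor(n / 2)))) {
    m <- ch[1:(n - p)] == ch[(p + 1):n]
    segs <- tandem_segments(m, p, min_identity)
    for (r in seq_len(nrow(segs))) {
      a <- segs$lo[r]; b <- segs$hi[r]
      span <- (b - a + 1L) + p
      copies <- span / p
      ident <- mean(m[a:b])
      if (copies >= min_copies && ident >= min_identity) {
        hits[[length(hits) + 1]] <- tibble::tibble(
          start = a - 1L, end = a - 1L + span,
          unit_length = p, copy_number = copies, identity = ident,
          total_length = span,
          unit_seq = paste(ch[a:(a + p - 1L)], collapse = "")
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          unit_length = integer(0), copy_number = numeric(0),
                          identity = numeric(0), total_length = integer(0),
                          unit_seq = character(0)))
  }
  out <- dplyr::bind_rows(hits)
  # prefer the smallest unit, then the longest span; drop nested re-finds
  out <- dplyr::arrange(out, .data$unit_length, dplyr::desc(.data$total_length))
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    acc <- which(keep[1:(i - 1)])
    ov <- pmin(out$end[i], out$end[acc]) - pmax(out$start[i], out$start[acc])
    if (any(ov > 0.5 * out$total_length[i])) keep[i] <- FALSE
  }
  dplyr::arrange(out[keep, ], .data$start)
}

# Candidate tandem segments of the lag-p match vector: exact match runs of
# length >= min(p, 12) seed a segment, which is greedily widened by
# absorbing neighbouring (mismatch run, match run) pairs while the overall
# identity stays at or above min_identity. Run-length encoding keeps the
# scan linear in the number of runs, not positions.
#' @noRd
tandem_segments <- function(m, p, min_identity) {
  r <- rle(m)
  k <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seed_min <- min(p, 12L)
  seeds <- which(r$values & r$lengths >= seed_min)
  lo <- integer(0); hi <- integer(0)
  done_until <- 0L
  for (sidx in seeds) {
    if (starts[sidx] <= done_until) next
    i <- sidx; j <- sidx
    matches <- r$lengths[sidx]; total <- r$lengths[sidx]
    repeat {
      moved <- FALSE
      if (j + 2L <= k && r$values[j + 2L]) {
        mm <- r$lengths[j + 1L]; mr <- r$lengths[j + 2L]
        if (mr / (mm + mr) >= min_identity &&
              (matches + mr) / (total + mm + mr) >= min_identity) {
          matches <- matches + mr; total <- total + mm + mr
          j <- j + 2L; moved <- TRUE
        }
      }
      if (i - 2L >= 1L && r$values[i - 2L]) {
        mm <- r$lengths[i - 1L]; mr <- r$lengths[i - 2L]
        if (mr / (mm + mr) >= min_identity &&
              (matches + mr) / (total + mm + mr) >= min_identity) {
          matches <- matches + mr; total <- total + mm + mr
          i <- i - 2L; moved <- TRUE
        }
      }
      if (!moved) break
    }
    lo <- c(lo, starts[i]); hi <- c(hi, ends[j])
    done_until <- ends[j]
  }
  tibble::tibble(lo = lo, hi = hi)
}

#' Find dispersed (interspersed) repeats by genome self-comparison
#'
#' Exact 12-mer seeding with gapless x-drop extension of the genome against
#' itself (both orientations); the trivial self-diagonal is excluded and
#' each duplication is reported once. A simplified stand-in for intragenomic
#' BLASTn with explicit length/identity thresholds instead of e-values.
#'
#' @param record [mitogenome()] or nucleotide string
#' @param min_len minimum repeat length (nt)
#' @param min_identity minimum identity of the pair
#' @return tibble: `start_a`, `end_a`, `start_b`, `end_b` (0-based
#'   half-open), `length`, `identity`, `orientation` (`same`/`inverted`)
#' @export
find_dispersed_repeats <- function(record, min_len = 35, min_identity = 0.76) {
  seq <- if (is_mitogenome(record)) record$sequence else record
  stopifnot(min_len >= 20)
  ch <- seq_chars(seq)
  n <- length(ch)
  fwd <- gapless_hits(ch, ch, k = 12, min_len, min_identity,
                      exclude_self_diagonal = TRUE)
  fwd$orientation <- rep("same", nrow(fwd))
  rc <- seq_chars(revcomp(seq))
  rev <- gapless_hits(ch, rc, k = 12, min_len, min_identity)
  if (nrow(rev) > 0) {
    # map revcomp coordinates back; drop palindromic self-overlaps and keep
    # one of each mirrored pair
    sb <- n - rev$end_b + 1L
    eb <- n - rev$start_b + 1L
    rev$start_b <- sb; rev$end_b <- eb
    rev <- rev[rev$start_a < rev$start_b |
                 (rev$start_a == rev$start_b & rev$end_a < rev$end_b), ]
    ov <- pmin(rev$end_a, rev$end_b) - pmax(rev$start_a, rev$start_b) + 1
    rev <- rev[ov < 0.5 * rev$length, ]
  }
  rev$orientation <- rep("inverted", nrow(rev))
  out <- dedupe_hits(dplyr::bind_rows(fwd, rev))
  out$start_a <- out$start_a - 1L; out$start_b <- out$start_b - 1L
  dplyr::arrange(out, .data$start_a)  # ends already exclusive after -1 shift
}
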