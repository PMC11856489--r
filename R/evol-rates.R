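#' Kimura 2-parameter distance from paired sequences
#'
#' P is the transition proportion, Q the transversion proportion over
#' compared sites; d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q). The distance
#' is undefined (`NaN`) when either log argument is non-positive.
#'
#' @param a either a `codon_alignment` (see [align_codon_aware()]), a
#'   tibble with `codon_a`/`codon_b` columns, or a nucleotide string
#' @param b second nucleotide string when `a` is a string
#' @return one-row tibble: `gene`, `id_a`, `id_b`, `sites`, `ts`, `tv`,
#'   `p`, `q`, `d_k2p`
#' @export
k2p <- function(a, b = NULL) {
  pc <- paired_chars(a, b)
  x <- pc$x; y <- pc$y
  n <- length(x)
  stopifnot(n >= 1)
  diff <- x != y
  ts <- sum(diff & is_transition(x, y))
  tv <- sum(diff) - ts
  p <- ts / n; q <- tv / n
  d <- if (1 - 2 * p - q <= 0 || 1 - 2 * q <= 0) NaN else
    -0.5 * log(1 - 2 * p - q) - 0.25 * log(1 - 2 * q)
  tibble::tibble(gene = pc$gene, id_a = pc$id_a, id_b = pc$id_b,
                 sites = n, ts = ts, tv = tv, p = p, q = q, d_k2p = d)
}

#' @noRd
paired_chars <- function(a, b) {
  if (inherits(a, "codon_alignment")) {
    return(list(x = seq_chars(paste(a$pairs$codon_a, collapse = "")),
                y = seq_chars(paste(a$pairs$codon_b, collapse = "")),
                gene = a$gene, id_a = a$id_a, id_b = a$id_b))
  }
  if (is.data.frame(a)) {
    return(list(x = seq_chars(paste(a$codon_a, collapse = "")),
                y = seq_chars(paste(a$codon_b, collapse = "")),
                gene = NA_character_, id_a = NA_character_,
                id_b = NA_character_))
  }
  stopifnot(is.character(a), is.character(b), nchar(a) == nchar(b))
  list(x = seq_chars(a), y = seq_chars(b), gene = NA_character_,
       id_a = NA_character_, id_b = NA_character_)
}

# --- Nei-Gojobori (1986) machinery -----------------------------------------

# Per-codon synonymous site count: at each position, the fraction of the 3
# single-base changes that preserve the amino acid. Changes creating a stop
# codon count as nonsynonymous, so every codon contributes exactly 3 sites.
.NG_SITES <- local({
  s <- stats::setNames(numeric(64), .CODONS)
  for (cd in .CODONS) {
    if (.GC4[cd] == "*") { s[cd] <- NA_real_; next }
    ch <- strsplit(cd, "")[[1]]
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(.BASES, ch[pos])) {
        alt <- ch; alt[pos] <- b
        alt <- paste(alt, collapse = "")
        if (.GC4[alt] != "*" && .GC4[alt] == .GC4[cd]) syn <- syn + 1
      }
    }
    s[cd] <- syn / 3
  }
  s
})

# Average synonymous/nonsynonymous differences between two codons over all
# mutational pathways; pathways passing through a stop codon are excluded
# (when every pathway is blocked, all are counted).
#' @noRd
codon_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- permutations_of(pos)
  tally <- function(order) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    sd <- 0; ndif <- 0; blocked <- FALSE
    for (p in order) {
      prev <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      nxt <- paste(cur, collapse = "")
      if (.GC4[nxt] == "*") blocked <- TRUE
      if (.GC4[nxt] == .GC4[prev]) sd <- sd + 1 else ndif <- ndif + 1
    }
    c(sd = sd, nd = ndif, blocked = as.numeric(blocked))
  }
  res <- t(vapply(perms, tally, c(sd = 0, nd = 0, blocked = 0)))
  open <- res[res[, "blocked"] == 0, , drop = FALSE]
  use <- if (nrow(open) > 0) open else res
  c(sd = mean(use[, "sd"]), nd = mean(use[, "nd"]))
}

#' @noRd
permutations_of <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# memoised pairwise codon difference table, filled on demand
.ng_cache <- new.env(parent = emptyenv())

#' @noRd
codon_path_diffs_cached <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- codon_path_diffs(c1, c2)
  assign(key, val, envir = .ng_cache)
  val
}

#' Nei-Gojobori (1986) Ka/Ks from paired codon columns
#'
#' Synonymous site counts follow the classic per-position fractions under
#' genetic code 4 (so S + N = 3 x codons compared, exactly); observed
#' differences average over all mutational pathways between each codon
#' pair, excluding pathways through stop codons. Proportions are corrected
#' with the Jukes-Cantor formula d = -3/4 ln(1 - 4p/3); p >= 3/4 yields
#' `NaN`. Codon pairs containing a stop codon are dropped.
#'
#' @param pairs a `codon_alignment`, or a tibble with `codon_a`/`codon_b`
#' @return one-row tibble: `gene`, `id_a`, `id_b`, `codons`, `s_sites`,
#'   `n_sites`, `sd`, `nd`, `ps`, `pn`, `ks`, `ka`, `ka_ks`
#' @export
ng86 <- function(pairs) {
  gene <- NA_character_; id_a <- NA_character_; id_b <- NA_character_
  if (inherits(pairs, "codon_alignment")) {
    gene <- pairs$gene; id_a <- pairs$id_a; id_b <- pairs$id_b
    pairs <- pairs$pairs
  }
  stopifnot(all(c("codon_a", "codon_b") %in% names(pairs)))
  ok <- !(pairs$codon_a %in% .STOP_CODONS | pairs$codon_b %in% .STOP_CODONS)
  ca <- pairs$codon_a[ok]; cb <- pairs$codon_b[ok]
  ncod <- length(ca)
  stopifnot(ncod >= 1)
  s_sites <- (sum(.NG_SITES[ca]) + sum(.NG_SITES[cb])) / 2
  n_sites <- 3 * ncod - s_sites
  diffs <- which(ca != cb)
  sd <- 0; nd <- 0
  for (i in diffs) {
    d <- codon_path_diffs_cached(ca[i], cb[i])
    sd <- sd + d[["sd"]]; nd <- nd + d[["nd"]]
  }
  ps <- if (s_sites > 0) sd / s_sites else NaN
  pn <- if (n_sites > 0) nd / n_sites else NaN
  jc <- function(p) if (is.nan(p) || p >= 0.75) NaN else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  tibble::tibble(gene = gene, id_a = id_a, id_b = id_b, codons = ncod,
                 s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd,
                 ps = ps, pn = pn, ks = ks, ka = ka,
                 ka_ks = if (!is.nan(ks) && ks > 0) ka / ks else NaN)
}

#' Per-gene summaries of pairwise distances
#'
#' @param tbl long tibble of pairwise results (e.g. bound rows of [k2p()]
#'   or [ng86()] over all species pairs)
#' @param value column to summarize (tidy-eval), e.g. `d_k2p` or `ka_ks`
#' @return tibble per gene: `n_pairs`, `n_defined`, `median`, `mean`,
#'   `q1`, `q3`, `iqr`; undefined (NaN/NA) pairs are dropped from the
#'   statistics and counted in `n_pairs - n_defined`
#' @export
summarize_gene <- function(tbl, value) {
  v <- rlang::enquo(value)
  tbl |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_defined = sum(is.finite(!!v)),
      median = stats::median((!!v)[is.finite(!!v)]),
      mean = mean((!!v)[is.finite(!!v)]),
      q1 = stats::quantile((!!v)[is.finite(!!v)], 0.25, names = FALSE),
      q3 = stats::quantile((!!v)[is.finite(!!v)], 0.75, names = FALSE),
      .groups = "drop") |>
    dplyr::mutate(iqr = .data$q3 - .data$q1)
}

#' Per-gene pairwise K2P and Ka/Ks across a cohort
#'
#' Runs codon-aware alignment, [k2p()] and [ng86()] for every species pair
#' and every requested gene.
#'
#' @param records list of annotated [mitogenome()] records
#' @param genes genes to compare; `gene_set = "14"` drops rps3 (a
#'   ribosomal protein, often excluded from respiratory-gene analyses)
#' @param gene_set `"15"` (default) or `"14"`
#' @return long tibble, one row per gene x pair, columns of [k2p()] and
#'   [ng86()] merged
#' @export
pairwise_gene_rates <- function(records, genes = NULL, gene_set = c("15", "14")) {
  gene_set <- match.arg(gene_set)
  if (is.null(genes)) {
    genes <- if (gene_set == "14") setdiff(.CORE_PCGS, "rps3") else .CORE_PCGS
  }
  ids <- purrr::map_chr(records, "id")
  prs <- utils::combn(seq_along(records), 2)
  rows <- list()
  for (g in genes) {
    cds <- purrr::map(records, function(r) {
      tryCatch(extract_cds(r, g), error = function(e) NULL)
    })
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      if (is.null(cds[[a]]) || is.null(cds[[b]])) next
      al <- tryCatch(align_codon_aware(cds[[a]], cds[[b]]),
                     error = function(e) NULL)
      if (is.null(al) || nrow(al$pairs) == 0) next
      kk <- k2p(al)
      ng <- ng86(al)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        kk, ng[, setdiff(names(ng), c("gene", "id_a", "id_b"))])
    }
  }
  dplyr::bind_rows(rows)
}

#' Mean K2P distance matrix over genes
#'
#' @param rates output of [pairwise_gene_rates()]
#' @param ids species order for the matrix (default: order of appearance)
#' @return symmetric numeric matrix of mean per-gene K2P distances
#' @export
k2p_distance_matrix <- function(rates, ids = NULL) {
  if (is.null(ids)) ids <- unique(c(rates$id_a, rates$id_b))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  avg <- rates |>
    dplyr::filter(is.finite(.data$d_k2p)) |>
    dplyr::group_by(.data$id_a, .data$id_b) |>
    dplyr::summarise(d = mean(.data$d_k2p), .groups = "drop")
  for (i in seq_len(nrow(avg))) {
    m[avg$id_a[i], avg$id_b[i]] <- avg$d[i]
    m[avg$id_b[i], avg$id_a[i]] <- avg$d[i]
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ via \pkg{ape}; negative branch lengths are clamped to zero
#' with a warning.
#'
#' @param mat symmetric distance matrix with labels
#' @return an unrooted `phylo` tree
#' @export
nj_tree <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 3, isSymmetric(unname(mat)))
  tr <- ape::nj(stats::as.dist(mat))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Write a square PHYLIP distance matrix
#' @param mat labelled symmetric matrix
#' @param path output path
#' @return `path`, invisibly
#' @export
write_phylip <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(mat)), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste0(formatC(rownames(mat)[i], width = -10),
                      paste(sprintf("%.6f", mat[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
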