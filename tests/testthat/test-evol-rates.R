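codons_of <- function(s) {
  n <- nchar(s) - nchar(s) %% 3
  starts <- seq(1, n - 2, by = 3)
  substring(s, starts, starts + 2)
}

mk_cds <- function(s, gene = "cox1", id = "sp") {
  structure(list(gene_name = gene, species_id = id, spliced_seq = s,
                 protein = NA, exon_offsets = integer(0), strand = "+",
                 complete = TRUE, internal_stop = FALSE),
            class = "coding_sequence")
}

test_that("codon-aware alignment keeps identical CDS and drops deletions", {
  set.seed(81)
  body <- paste(sample(c("GCT", "AAA", "TGT", "GAT", "TTC", "GGT"),
                       30, replace = TRUE), collapse = "")
  s <- paste0("ATG", body, "TAA")
  al <- align_codon_aware(mk_cds(s), mk_cds(s))
  expect_equal(nrow(al$pairs), 31)          # stop stripped, all retained
  expect_true(all(al$pairs$codon_a == al$pairs$codon_b))

  # remove one codon from the second copy: exactly one column lost
  s2 <- paste0("ATG", substr(body, 1, 30), substr(body, 34, nchar(body)),
               "TAA")
  al2 <- align_codon_aware(mk_cds(s), mk_cds(s2))
  expect_equal(nrow(al2$pairs), 30)
})

test_that("K2P closed form and degenerate cases", {
  s <- strrep("ACGT", 50)
  expect_equal(k2p(s, s)$d_k2p, 0)

  # 100 sites, 20 transitions, 10 transversions
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 70), strrep("G", 20), strrep("C", 10))
  d <- k2p(a, b)
  expect_equal(d$p, 0.2)
  expect_equal(d$q, 0.1)
  expect_equal(d$d_k2p, -0.5 * log(1 - 2 * 0.2 - 0.1) - 0.25 * log(1 - 0.2),
               tolerance = 1e-12)

  # saturation: log-domain violation is NaN, not a number
  expect_true(is.nan(k2p(strrep("A", 10), strrep("G", 10))$d_k2p))
})

test_that("K2P distance is monotone in P and in Q inside its domain", {
  ps <- seq(0.01, 0.3, by = 0.01)
  dd <- vapply(ps, function(p) -0.5 * log(1 - 2 * p - 0.05) -
                 0.25 * log(1 - 0.1), numeric(1))
  expect_true(all(diff(dd) > 0))
  qs <- seq(0.01, 0.3, by = 0.01)
  dq <- vapply(qs, function(q) -0.5 * log(1 - 2 * 0.05 - q) -
                 0.25 * log(1 - 2 * q), numeric(1))
  expect_true(all(diff(dq) > 0))
  # and the implementation agrees with the closed form on a grid
  for (p in c(0.05, 0.15)) for (q in c(0.05, 0.1)) {
    n <- 200
    a <- strrep("A", n)
    b <- paste0(strrep("A", round(n * (1 - p - q))), strrep("G", round(n * p)),
                strrep("T", round(n * q)))
    expect_equal(k2p(a, b)$d_k2p,
                 -0.5 * log(1 - 2 * p - q) - 0.25 * log(1 - 2 * q),
                 tolerance = 1e-12)
  }
})

test_that("K2P estimate recovers the simulated distance", {
  set.seed(82)
  ds <- replicate(12, {
    anc <- random_dna_str(10000)
    der <- sim_evolve(anc, 0.1, kappa = 2)
    k2p(anc, der)$d_k2p
  })
  se <- sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - 0.1), 3 * se + 0.002)
})

# ---- independent NG86 oracle ----------------------------------------------
code4 <- function(codon) {
  gc <- Biostrings::getGeneticCode("4")
  unname(gc[codon])
}

oracle_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
    alt <- ch; alt[pos] <- b
    altc <- paste(alt, collapse = "")
    if (code4(altc) != "*" && code4(altc) == code4(codon)) syn <- syn + 1
  }
  syn / 3
}

oracle_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  perms <- if (length(pos) == 1) list(pos) else {
    do.call(c, lapply(seq_along(pos), function(i) {
      lapply(if (length(pos) == 2) list(pos[-i]) else {
        p2 <- pos[-i]
        list(p2, rev(p2))
      }, function(rest) c(pos[i], rest))
    }))
  }
  eval_path <- function(ord) {
    cur <- strsplit(c1, "")[[1]]; tgt <- strsplit(c2, "")[[1]]
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      before <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      after <- paste(cur, collapse = "")
      if (code4(after) == "*") blocked <- TRUE
      if (code4(after) == code4(before)) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd, nd, blocked)
  }
  res <- t(sapply(perms, eval_path))
  ok <- res[res[, 3] == 0, , drop = FALSE]
  use <- if (nrow(ok) > 0) ok else res
  c(mean(use[, 1]), mean(use[, 2]))
}

test_that("NG86 equals the exhaustive pathway oracle on random codon pairs", {
  set.seed(83)
  non_stop <- setdiff(names(Biostrings::getGeneticCode("4")),
                      c("TAA", "TAG"))
  ca <- sample(non_stop, 100, replace = TRUE)
  cb <- sample(non_stop, 100, replace = TRUE)
  got <- ng86(tibble::tibble(codon_a = ca, codon_b = cb))
  s_oracle <- (sum(vapply(ca, oracle_sites, numeric(1))) +
                 sum(vapply(cb, oracle_sites, numeric(1)))) / 2
  d_oracle <- rowSums(vapply(seq_along(ca), function(i) {
    oracle_diffs(ca[i], cb[i])
  }, numeric(2)))
  expect_equal(got$s_sites, s_oracle, tolerance = 1e-10)
  expect_equal(got$n_sites, 3 * 100 - s_oracle, tolerance = 1e-10)
  expect_equal(got$sd, d_oracle[1], tolerance = 1e-10)
  expect_equal(got$nd, d_oracle[2], tolerance = 1e-10)
  # S + N is exactly 3 x codons
  expect_equal(got$s_sites + got$n_sites, 3 * got$codons)
})

test_that("NG86 hand cases: identity and the TTA/TTG synonymous pair", {
  same <- ng86(tibble::tibble(codon_a = c("ATG", "GCT"),
                              codon_b = c("ATG", "GCT")))
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)

  leu <- ng86(tibble::tibble(codon_a = "TTA", codon_b = "TTG"))
  expect_equal(leu$sd, 1)
  expect_equal(leu$nd, 0)
  expect_equal(leu$ka, 0)
})

test_that("purifying-selection simulations give Ka/Ks below 1", {
  set.seed(84)
  below <- replicate(12, {
    ncod <- 1500
    pool <- setdiff(names(Biostrings::getGeneticCode("4")), c("TAA", "TAG"))
    anc <- paste0("ATG", paste(sample(pool, ncod, TRUE), collapse = ""), "TAA")
    der <- sim_evolve(anc, 0.15, kappa = 2, omega = 0.2)
    r <- ng86(tibble::tibble(codon_a = codons_of(anc), codon_b = codons_of(der)))
    r$ka_ks
  })
  expect_true(all(is.finite(below)))
  expect_true(all(below < 1))
})

test_that("gene summaries: single pair and all-equal degenerate cases", {
  one <- tibble::tibble(gene = "atp6", d_k2p = 0.12)
  s <- summarize_gene(one, d_k2p)
  expect_equal(s$median, 0.12)
  flat <- tibble::tibble(gene = rep("cob", 4), d_k2p = rep(0.05, 4))
  expect_equal(summarize_gene(flat, d_k2p)$iqr, 0)
})

test_that("a fast-evolving gene ranks first by median K2P", {
  set.seed(85)
  rows <- list()
  for (rep in 1:6) {
    slow_anc <- random_dna_str(2000)
    fast_anc <- random_dna_str(2000)
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene = "slow", d_k2p = k2p(slow_anc, sim_evolve(slow_anc, 0.02))$d_k2p)
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene = "fast", d_k2p = k2p(fast_anc, sim_evolve(fast_anc, 0.2))$d_k2p)
  }
  s <- summarize_gene(dplyr::bind_rows(rows), d_k2p)
  expect_gt(s$median[s$gene == "fast"], s$median[s$gene == "slow"])
})

test_that("NJ: 3-taxon closed form, additive 4-taxon recovery, UPGMA accord", {
  m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(m)
  # closed three-point formulas: x = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length[order(tr$edge[, 2])][1:3], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))

  # additive matrix on ((a,b),(c,d))
  tru <- ape::read.tree(text = "((a:1,b:2):1.5,(c:1,d:3):0);")
  m4 <- as.matrix(ape::cophenetic.phylo(tru))[letters[1:4], letters[1:4]]
  tr4 <- ape::unroot(nj_tree(m4))
  expect_equal(ape::dist.topo(tr4, ape::unroot(tru)), 0,
               ignore_attr = TRUE)

  # ultrametric distances: NJ topology equals UPGMA topology
  tru_u <- ape::read.tree(text = "((a:1,b:1):2,(c:2,d:2):1);")
  mu <- as.matrix(ape::cophenetic.phylo(tru_u))[letters[1:4], letters[1:4]]
  up <- ape::as.phylo(stats::hclust(stats::as.dist(mu), method = "average"))
  expect_equal(ape::dist.topo(ape::unroot(nj_tree(mu)), ape::unroot(up)), 0,
               ignore_attr = TRUE)
})
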