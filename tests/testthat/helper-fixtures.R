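# Shared fixtures. Simulation is the expensive step, so cohorts are built
# once per test run and memoised here.

random_dna_str <- function(n, p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- make_fixture(name)
  }
  .fixture_cache[[name]]
}

# a small hand-built annotated genome used across IO/composition tests:
# 1000 nt, one 2-exon gene (cox1) with a join-gap intron carrying a HEG,
# one tRNA, one un_ORF
tiny_record <- function() {
  set.seed(404)
  seq <- random_dna_str(1000)
  # cox1 exons [100,160) + [310,370), intron [160,310), heg [190,280)
  exon1 <- "ATGGCTGCTGCAGCTGCAGCTGCTAAAGCTGCAGCTGCAGCTGCTGCAGCTGCAGCAGCT"
  exon2 <- "GCAGCTGCTGCAGCTGCAGCTGCTAAAGCTGCAGCTGCAGCTGCTGCAGCTGCAGCATAA"
  seq <- paste0(substr(seq, 1, 100), exon1, substr(seq, 161, 310),
                exon2, substr(seq, 371, 1000))
  seq <- paste0(substr(seq, 1, 160), "GT", substr(seq, 163, 1000)) # intron 5'
  feats <- tibble::tibble(
    category = c("core_pcg", "intron", "heg", "trna", "un_orf"),
    gene_name = c("cox1", "cox1-i1", "cox1-i1-heg", "trnA", "orf99"),
    strand = "+",
    parent = c(NA, "cox1", "cox1", NA, NA),
    segments = list(
      tibble::tibble(start = c(100L, 310L), end = c(160L, 370L)),
      tibble::tibble(start = 160L, end = 310L),
      tibble::tibble(start = 190L, end = 280L),
      tibble::tibble(start = 500L, end = 572L),
      tibble::tibble(start = 650L, end = 850L)
    )
  )
  mitogenome("tiny1", seq, feats, organism = "Tinyella exempli")
}
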