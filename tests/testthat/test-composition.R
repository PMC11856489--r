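test_that("skew formulas and undefined denominators", {
  at <- base_composition("AATT")
  expect_equal(at$at_skew, 0)
  expect_true(is.nan(at$gc_skew))

  gg <- base_composition("GGGC")
  expect_equal(gg$gc_skew, (3 - 1) / (3 + 1))

  aa <- base_composition("AAAT")
  expect_equal(aa$at_skew, 0.5)
  expect_equal(aa$gc_content, 0)
})

test_that("skews flip sign and GC content is invariant under revcomp", {
  set.seed(31)
  for (i in 1:10) {
    s <- random_dna_str(500, c(A = 0.4, C = 0.1, G = 0.2, T = 0.3))
    b1 <- base_composition(s)
    b2 <- base_composition(revcomp(s))
    expect_equal(b1$at_skew, -b2$at_skew)
    expect_equal(b1$gc_skew, -b2$gc_skew)
    expect_equal(b1$gc_content, b2$gc_content)
  }
})

test_that("decomposition assigns every position once, HEG as overlay", {
  rec <- tiny_record()
  d <- decompose_genome(rec)
  expect_equal(d$core_pcg, 120)       # two 60 nt exons
  expect_equal(d$intronic, 150)
  expect_equal(d$heg, 90)             # inside the intron, not subtracted
  expect_equal(d$rna_region, 72)
  expect_equal(d$un_orf, 200)
  expect_equal(d$core_pcg + d$rna_region + d$intronic + d$un_orf +
                 d$intergenic, d$total)

  # bare 300 nt gene in a 1000 nt genome
  r2 <- mitogenome("g", strrep("ACGT", 250), tibble::tibble(
    category = "core_pcg", gene_name = "cob", strand = "+",
    parent = NA_character_,
    segments = list(tibble::tibble(start = 100L, end = 400L))))
  d2 <- decompose_genome(r2)
  expect_equal(d2$core_pcg, 300)
  expect_equal(d2$intergenic, 700)
})

test_that("decomposition equals simulator ground truth on every genome", {
  sim <- cached_fixture("conserved7")
  for (rec in sim$records) {
    d <- decompose_genome(rec)
    tr <- sim$truth$components[sim$truth$components$species_id == rec$id, ]
    expect_equal(d$core_pcg, tr$core_pcg)
    expect_equal(d$rna_region, tr$rna_region)
    expect_equal(d$intronic, tr$intronic)
    expect_equal(d$un_orf, tr$un_orf)
    expect_equal(d$intergenic, tr$intergenic)
    expect_equal(d$heg, tr$heg)
    expect_equal(d$core_pcg + d$rna_region + d$intronic + d$un_orf +
                   d$intergenic, rec$length)
  }
})

# exhaustive perfect-array scan: every (start, period) with >= min_copies
# exact copies, reported as maximal spans
perfect_tandem_oracle <- function(s, min_unit, max_unit, min_copies) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  found <- list()
  for (p in min_unit:max_unit) {
    m <- ch[1:(n - p)] == ch[(p + 1):n]
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      span <- r$lengths[i] + p
      if (span / p >= min_copies) {
        found[[length(found) + 1]] <-
          c(start = starts[i] - 1, span = span, unit = p)
      }
    }
  }
  do.call(rbind, found)
}

test_that("tandem detector recovers planted arrays exactly", {
  set.seed(61)
  u11 <- random_dna_str(11); u25 <- random_dna_str(25); u68 <- random_dna_str(68)
  s <- paste0(random_dna_str(800), strrep(u11, 3), random_dna_str(700),
              paste0(strrep(u25, 2), substr(u25, 1, 13)),
              random_dna_str(900), strrep(u68, 2), random_dna_str(800))
  got <- find_tandem_repeats(s, min_identity = 1)
  oracle <- perfect_tandem_oracle(s, 10, 200, 1.9)
  # keep the smallest-unit representative of each oracle span
  okeep <- oracle[!duplicated(oracle[, "start"]), , drop = FALSE]
  expect_equal(nrow(got), 3)
  expect_setequal(got$unit_length, c(11, 25, 68))
  expect_true(all(got$identity == 1))
  for (i in seq_len(nrow(got))) {
    hit <- okeep[okeep[, "unit"] == got$unit_length[i], , drop = FALSE]
    expect_equal(got$start[i], unname(hit[1, "start"]))
    expect_equal(got$total_length[i], unname(hit[1, "span"]))
  }
})

test_that("two perfect copies of a 68 nt unit pass the 1.9-copy threshold", {
  set.seed(62)
  u <- random_dna_str(68)
  s <- paste0(random_dna_str(300), u, u, random_dna_str(300))
  got <- find_tandem_repeats(s)
  expect_equal(nrow(got), 1)
  expect_gte(got$copy_number, 1.9)
  expect_equal(got$unit_length, 68L)
})

test_that("dispersed repeats: inverted duplication, absence, and noisy copy", {
  set.seed(63)
  X <- random_dna_str(200)
  g <- paste0(X, random_dna_str(2000), revcomp(X))
  hit <- find_dispersed_repeats(g)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$orientation, "inverted")
  expect_gte(hit$identity, 0.99)
  expect_gte(hit$length, 195)

  expect_equal(nrow(find_dispersed_repeats(random_dna_str(3000))), 0)

  Y <- random_dna_str(100)
  g2 <- paste0(random_dna_str(1000), Y, random_dna_str(1000),
               mutate_seq(Y, 0.1), random_dna_str(1000))
  hit2 <- find_dispersed_repeats(g2)
  expect_equal(nrow(hit2), 1)
  expect_equal(hit2$orientation, "same")
  expect_true(hit2$identity > 0.82 && hit2$identity < 1)
  # repeat proportion bounded
  expect_true(sum(hit2$length) / nchar(g2) >= 0 &&
                sum(hit2$length) / nchar(g2) <= 1)
})
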