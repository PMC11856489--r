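# build a one-gene record with an intron after `before_nt` coding
# nucleotides of a 30-codon gene
intron_record <- function(before_nt, id = "q", extra_5prime_codons = 0) {
  set.seed(100 + before_nt)
  pool <- c("GCT", "AAA", "TGT", "GAT", "TTC", "GGT", "CCA", "ATT")
  body <- sample(pool, 28, replace = TRUE)
  if (extra_5prime_codons > 0) {
    # tryptophan codons: absent from the pool, so the aligner must gap them
    body <- c(rep("TGG", extra_5prime_codons), body)
  }
  coding <- paste0("ATG", paste(body, collapse = ""), "TAA")
  intron <- paste0("GT", strrep("ACTT", 60), "AG")
  g <- paste0(substr(coding, 1, before_nt), intron,
              substr(coding, before_nt + 1, nchar(coding)))
  glen <- nchar(g)
  mitogenome(id, paste0("AAAA", g, "TTTT"), tibble::tibble(
    category = c("core_pcg", "intron"),
    gene_name = c("cob", "cob-i1"),
    strand = "+", parent = c(NA, "cob"),
    segments = list(
      tibble::tibble(start = c(4L, 4L + before_nt + nchar(intron)),
                     end = c(4L + before_nt, 4L + glen)),
      tibble::tibble(start = 4L + before_nt,
                     end = 4L + before_nt + nchar(intron)))))
}

test_that("intron phase follows local_pos mod 3 (0 = between codons)", {
  for (lp in c(3L, 4L, 5L, 30L)) {
    intr <- extract_introns(intron_record(lp))
    expect_equal(intr$local_pos, lp)
    expect_equal(intr$phase, lp %% 3)
    expect_equal(intr$first_dint, "GT")
  }
})

test_that("flanks come from the spliced exonic sequence", {
  rec <- intron_record(30L)
  intr <- extract_introns(rec)
  cds <- extract_cds(rec, "cob", translate = FALSE)
  expect_equal(intr$flank_up, substr(cds$spliced_seq, 16, 30))
  expect_equal(intr$flank_down, substr(cds$spliced_seq, 31, 45))
  expect_false(intr$flank_truncated)
  # near the gene start the upstream flank is short and flagged
  intr2 <- extract_introns(intron_record(6L))
  expect_equal(nchar(intr2$flank_up), 6)
  expect_true(intr2$flank_truncated)
})

test_that("reference mapping: identity, and gap arithmetic for insertions", {
  q <- extract_cds(intron_record(30L), "cob", translate = FALSE)
  expect_equal(map_to_reference(30L, q, q), 30L)

  # query carries 6 extra nt (2 codons) 5' of the intron
  q2 <- extract_cds(intron_record(30L, extra_5prime_codons = 2), "cob",
                    translate = FALSE)
  ref <- extract_cds(intron_record(30L), "cob", translate = FALSE)
  expect_equal(map_to_reference(36L, q2, ref), 30L)

  # nucleotide route used for rRNA hosts
  expect_equal(map_to_reference(30L, q, q, codon_aware = FALSE), 30L)
})

test_that("IPS tolerance clustering follows single linkage with max gap 3", {
  base <- tibble::tibble(
    species_id = c("s1", "s2", "s3"), host_gene = "cob",
    host_category = "core_pcg", local_pos = c(100L, 102L, 103L),
    ref_pos = c(100L, 102L, 103L), length = 1200L, phase = 1L,
    flank_up = "A", flank_down = "C", first_dint = "GT", has_heg = FALSE)
  expect_equal(nrow(cluster_ips(base, tolerance = 3)$ips), 1)

  two <- base[1:2, ]
  two$ref_pos <- c(100L, 104L)
  expect_equal(nrow(cluster_ips(two, tolerance = 3)$ips), 2)

  chain <- base
  chain$ref_pos <- c(100L, 103L, 106L)
  cat <- cluster_ips(chain, tolerance = 3)
  expect_equal(nrow(cat$ips), 1)   # chained: adjacent gaps are both 3
  expect_equal(cat$ips$n_species, 3)
  expect_true(cat$ips$shared)
})

test_that("clustering is invariant to input order and IPS ids are stable", {
  sim <- cached_fixture("conserved7")
  mapped <- map_introns_to_reference(sim$records, reference = "A_ref")
  cat1 <- cluster_ips(mapped, tolerance = 3, reference = "A_ref")
  set.seed(123)
  cat2 <- cluster_ips(mapped[sample(nrow(mapped)), ], tolerance = 3,
                      reference = "A_ref")
  expect_equal(cat1$ips, cat2$ips)
  # conservation: member counts sum to total introns
  expect_equal(sum(cat1$ips$n_introns), nrow(mapped))
  expect_equal(sum(cat1$per_species$n_introns), nrow(mapped))
})

test_that("tolerance 0 equals the distinct (gene, position) oracle and truth", {
  sim <- cached_fixture("conserved7")
  mapped <- map_introns_to_reference(sim$records, reference = "A_ref")
  cat0 <- cluster_ips(mapped, tolerance = 0, reference = "A_ref")
  oracle <- nrow(dplyr::distinct(mapped, .data$host_gene, .data$ref_pos))
  expect_equal(nrow(cat0$ips), oracle)
  # exact agreement with the simulator's shared-intron matrix
  truth <- sim$truth$ips_matrix
  expect_equal(nrow(cat0$ips), nrow(truth))
  sp <- sort(sim$truth$tree$tip.label)
  tm <- as.matrix(truth[order(truth$gene, truth$offset), sp])
  pm0 <- dplyr::left_join(cat0$ips, cat0$presence, by = "ips_id")
  pm <- as.matrix(pm0[order(pm0$gene, pm0$ref_pos), sp])
  expect_equal(unname(pm), unname(tm))
  expect_equal(sum(cat0$ips$shared),
               sum(rowSums(tm) >= 2))
})

test_that("classification: sharing, phase totals, and length histogram", {
  sim <- cached_fixture("conserved7")
  mapped <- map_introns_to_reference(sim$records, reference = "A_ref")
  cat <- cluster_ips(mapped, tolerance = 3, reference = "A_ref")
  cls <- classify_ips(cat)
  expect_equal(cls$n_shared + cls$n_specific, nrow(cat$ips))
  # every-IPS-singleton catalog has zero shared sets
  solo <- mapped[!duplicated(mapped$host_gene), ]
  solo$ref_pos <- seq(100L, by = 1000L, length.out = nrow(solo))
  solo$species_id <- paste0("only", seq_len(nrow(solo)))
  expect_equal(classify_ips(cluster_ips(solo, 3))$n_shared, 0)
  # phase histogram counts PCG-hosted introns only
  expect_equal(sum(cls$phase_hist$n_introns),
               sum(!is.na(mapped$phase)))
  # simulated intron lengths are enriched in the 1000-2000 nt region
  lh <- cls$length_hist |>
    dplyr::group_by(.data$bin_lo) |>
    dplyr::summarise(n = sum(.data$n_introns))
  expect_equal(lh$bin_lo[which.max(lh$n)] %in% c(1000, 1500), TRUE)
})

test_that("flank profile: consensus, GT dinucleotide, planted motif", {
  ident <- tibble::tibble(
    flank_up = rep("ACGTACGTACGTACG", 4),
    flank_down = rep("TTTTGGGGCCCCAAA", 4),
    first_dint = rep("GT", 4))
  pr <- flank_profile(ident)
  expect_equal(pr$consensus, paste0("ACGTACGTACGTACG", "TTTTGGGGCCCCAAA"))
  expect_true(all(pr$freq$freq %in% c(0, 1)))
  expect_equal(pr$dinucleotide$freq[pr$dinucleotide$first_dint == "GT"], 1)

  # planted motif at positions -2..-1 against random background
  set.seed(131)
  n <- 40
  planted <- tibble::tibble(
    flank_up = vapply(seq_len(n), function(i)
      paste0(random_dna_str(13), "CG"), character(1)),
    flank_down = vapply(seq_len(n), function(i) random_dna_str(15),
                        character(1)),
    first_dint = "GT")
  pr2 <- flank_profile(planted)
  expect_equal(substr(pr2$consensus, 14, 15), "CG")
})
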