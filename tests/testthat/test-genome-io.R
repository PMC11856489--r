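gb_text <- function(id, len, seq, feature_lines) {
  c(sprintf("LOCUS       %s %d bp    DNA     circular   PLN", id, len),
    "DEFINITION  test record.",
    "SOURCE      mitochondrion",
    "  ORGANISM  Testus testus",
    "FEATURES             Location/Qualifiers",
    feature_lines,
    "ORIGIN",
    vapply(seq(1, nchar(seq), by = 60), function(st) {
      bp <- seq(st, min(st + 59, nchar(seq)), by = 10)
      sprintf("%9d %s", st,
              paste(substring(tolower(seq), bp, pmin(bp + 9, nchar(seq))),
                    collapse = " "))
    }, character(1)),
    "//")
}

test_that("join() gaps become intron features with the host as parent", {
  set.seed(1)
  seq <- random_dna_str(2000)
  lines <- gb_text("rec1", 2000, seq, c(
    "     CDS             join(101..300,1501..1900)",
    '                     /gene="COX1"'))
  tf <- withr::local_tempfile(lines = lines)
  rec <- read_genbank(tf)[[1]]
  cx <- rec$features[rec$features$gene_name == "cox1", ]
  expect_equal(cx$category, "core_pcg")
  expect_equal(nrow(cx$segments[[1]]), 2)
  intr <- rec$features[rec$features$category == "intron", ]
  expect_equal(nrow(intr), 1)
  expect_equal(intr$parent, "cox1")
  expect_equal(intr$segments[[1]]$start, 300L)
  expect_equal(intr$segments[[1]]$end, 1500L)
})

test_that("gene labels are folded through the synonym table", {
  expect_equal(normalize_gene_name("ND4L"), "nad4L")
  expect_equal(normalize_gene_name(c("ATP6", "atpase 6", "cytb", "CO1")),
               c("atp6", "atp6", "cob", "cox1"))
  expect_true(is.na(normalize_gene_name("orf1337")))
})

test_that("strict mode rejects ambiguity codes, lax mode maps them to N", {
  lines <- gb_text("amb1", 12, "ACGTRYACGTAC",
                   c("     rRNA            1..10", '                     /gene="rnl"'))
  tf <- withr::local_tempfile(lines = lines)
  rec <- read_genbank(tf)[[1]]
  expect_equal(substr(rec$sequence, 5, 6), "NN")
  expect_error(read_genbank(tf, strict = TRUE), "ambiguity")
})

test_that("extract_cds splices, reverse-complements and translates (code 4)", {
  r <- mitogenome("x", "ATGTTAGGGGGG", tibble::tibble(
    category = "core_pcg", gene_name = "atp6", strand = "+",
    parent = NA_character_,
    segments = list(tibble::tibble(start = 0L, end = 6L))))
  cds <- extract_cds(r, "atp6")
  expect_equal(cds$spliced_seq, "ATGTTA")
  expect_equal(cds$protein, "ML")

  # two exons: 3 coding nt precede the intron
  r2 <- mitogenome("x", "ATGCCCCCCCTAA", tibble::tibble(
    category = "core_pcg", gene_name = "atp6", strand = "+",
    parent = NA_character_,
    segments = list(tibble::tibble(start = c(0L, 10L), end = c(3L, 13L)))))
  cds2 <- extract_cds(r2, "atp6")
  expect_equal(cds2$exon_offsets, 3L)
  expect_equal(cds2$spliced_seq, "ATGTAA")

  # minus strand single exon
  r3 <- mitogenome("x", "TTACAT", tibble::tibble(
    category = "core_pcg", gene_name = "atp6", strand = "-",
    parent = NA_character_,
    segments = list(tibble::tibble(start = 0L, end = 6L))))
  expect_equal(extract_cds(r3, "atp6")$spliced_seq, "ATGTAA")
})

test_that("minus-strand extraction equals plus-strand on the mirrored record", {
  set.seed(21)
  for (i in 1:5) {
    n <- 300L
    s <- random_dna_str(n)
    a <- sample(0:100, 1); b <- a + 3 * sample(20:40, 1)
    rplus <- mitogenome("p", s, tibble::tibble(
      category = "core_pcg", gene_name = "cob", strand = "+",
      parent = NA_character_,
      segments = list(tibble::tibble(start = a, end = b))))
    rminus <- mitogenome("m", revcomp(s), tibble::tibble(
      category = "core_pcg", gene_name = "cob", strand = "-",
      parent = NA_character_,
      segments = list(tibble::tibble(start = n - b, end = n - a))))
    expect_equal(extract_cds(rminus, "cob")$spliced_seq,
                 extract_cds(rplus, "cob")$spliced_seq)
  }
})

test_that("GenBank write -> read round-trips features and sequence", {
  recs <- list(tiny_record(), cached_fixture("conserved7")$records[[2]])
  for (rec in recs) {
    tf <- withr::local_tempfile(fileext = ".gb")
    write_genbank(rec, tf)
    back <- read_genbank(tf)[[1]]
    expect_equal(back$sequence, rec$sequence)
    expect_equal(back$id, rec$id)
    f1 <- dplyr::arrange(rec$features, category, gene_name)
    f2 <- dplyr::arrange(back$features, category, gene_name)
    expect_equal(f1$category, f2$category)
    expect_equal(f1$gene_name, f2$gene_name)
    expect_equal(f1$parent, f2$parent)
    for (i in seq_len(nrow(f1))) {
      expect_equal(as.data.frame(f1$segments[[i]]),
                   as.data.frame(f2$segments[[i]]))
    }
  }
})

test_that("origin-wrapping features trigger rotation so nothing wraps", {
  set.seed(5)
  seq <- random_dna_str(1000)
  lines <- gb_text("wrap1", 1000, seq, c(
    "     CDS             join(901..1000,1..200)",
    '                     /gene="nad3"'))
  tf <- withr::local_tempfile(lines = lines)
  rec <- read_genbank(tf)[[1]]
  seg <- rec$features$segments[[which(rec$features$gene_name == "nad3")]]
  expect_equal(sum(seg$end - seg$start), 300)
  expect_true(all(seg$end > seg$start))
  # rotated sequence still contains the gene contiguously at the new origin
  expect_equal(substr(rec$sequence, 1, 300),
               paste0(substr(seq, 901, 1000), substr(seq, 1, 200)))
})

test_that("sum of spliced + intron lengths equals genomic footprints", {
  rec <- cached_fixture("conserved7")$records[[1]]
  feats <- rec$features
  hosts <- feats[feats$category %in% c("core_pcg", "rrna"), ]
  for (g in hosts$gene_name) {
    cds <- extract_cds(rec, g, translate = FALSE)
    introns <- feats[feats$category == "intron" & !is.na(feats$parent) &
                       feats$parent == g, ]
    intron_nt <- sum(vapply(introns$segments,
                            function(s) sum(s$end - s$start), numeric(1)))
    seg <- hosts$segments[[which(hosts$gene_name == g)]]
    footprint <- max(seg$end) - min(seg$start)
    expect_equal(nchar(cds$spliced_seq) + intron_nt, footprint)
  }
})

# independent six-frame scan: tokenise codons as start/stop/other and walk
orf_oracle_count <- function(seq, min_aa) {
  n <- nchar(seq)
  total <- 0L
  for (s in c(seq, revcomp(seq))) {
    for (frame in 0:2) {
      sub <- substr(s, frame + 1, n)
      ncod <- nchar(sub) %/% 3
      if (ncod == 0) next
      codons <- substring(sub, 3 * (0:(ncod - 1)) + 1, 3 * (0:(ncod - 1)) + 3)
      tok <- ifelse(codons %in% c("TAA", "TAG"), "X",
                    ifelse(codons %in% c("ATG", "TTG", "GTG", "TTA"),
                           "S", "O"))
      open <- FALSE; start_at <- NA
      for (i in seq_along(tok)) {
        if (tok[i] == "X") {
          if (open && (i - start_at) >= min_aa) total <- total + 1L
          open <- FALSE
        } else if (tok[i] == "S" && !open) {
          open <- TRUE; start_at <- i
        }
      }
    }
  }
  total
}

test_that("find_orfs matches the exhaustive six-frame oracle", {
  r <- mitogenome("t", "ATGAAATAAACG")
  orfs <- find_orfs(r, min_aa = 2)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$length_aa, 2L)

  expect_equal(nrow(find_orfs(mitogenome("n", strrep("N", 500)), 5)), 0)

  set.seed(99)
  s <- random_dna_str(10000)
  for (min_aa in c(30, 60)) {
    got <- find_orfs(mitogenome("r", s), min_aa = min_aa)
    expect_equal(nrow(got), orf_oracle_count(s, min_aa))
  }
})

test_that("TSV tables are deterministic, rounded, and round-trip", {
  tb <- tibble::tibble(id = c("a", "b"), x = c(1.234567, 2),
                       y = c(10L, 20L))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_table_tsv(tb, tf)
  back <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(back$x, c(1.2346, 2))
  expect_equal(names(back), names(tb))
  # empty input -> header-only file
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_table_tsv(tb[0, ], tf2)
  expect_equal(readLines(tf2), "id\tx\ty")
})
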