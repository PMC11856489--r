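# Genetic-code machinery shared across modules. Everything here is keyed to
# NCBI translation table 4 (mold/protozoan mitochondrial code): TGA = Trp,
# stops are TAA and TAG only.

.BASES <- c("A", "C", "G", "T")

#' The 64 codons in fixed lexicographic order
#' @noRd
.CODONS <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0)) |>
  sort()

# codon -> amino acid (one letter, "*" = stop) under code 4
.GC4 <- {
  gc <- Biostrings::getGeneticCode("4")
  stats::setNames(as.character(gc), names(gc))[.CODONS]
}

.STOP_CODONS <- names(.GC4)[.GC4 == "*"]

# amino acid -> synonymous family size under code 4 (stops excluded)
.FAMILY_SIZE <- table(.GC4[.GC4 != "*"])

#' Translate a nucleotide string under the mold mitochondrial code
#'
#' Codons containing N (or any non-ACGT character) translate to `X`;
#' TGA translates to tryptophan.
#'
#' @param nt nucleotide string, length a multiple of 3 (trailing partial
#'   codon is dropped with a warning)
#' @return single amino-acid string, stops as `*`
#' @export
translate_code4 <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1)
  n <- nchar(nt)
  if (n %% 3 != 0) {
    warning("sequence length not a multiple of 3; trailing ", n %% 3,
            " nt dropped")
    n <- n - n %% 3
  }
  if (n == 0) return("")
  codons <- codon_split(substr(nt, 1, n))
  aa <- unname(.GC4[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' @noRd
codon_split <- function(nt) {
  n <- nchar(nt)
  if (n < 3) return(character(0))
  starts <- seq(1, n - 2, by = 3)
  substring(nt, starts, starts + 2)
}

#' Reverse complement of a nucleotide string
#' @param nt nucleotide string over A,C,G,T,N (case-insensitive)
#' @return reverse complement, uppercase
#' @export
revcomp <- function(nt) {
  stopifnot(is.character(nt))
  vapply(nt, function(x) {
    x <- chartr("acgtnACGTN", "TGCANTGCAN", x)
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
seq_chars <- function(nt) strsplit(toupper(nt), "", fixed = TRUE)[[1]]

#' @noRd
is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' @noRd
random_dna <- function(n, p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
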