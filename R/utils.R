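#' @importFrom stats rpois rnorm runif sd setNames aggregate cor
#' @importFrom utils adist head combn
NULL

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a

DNA_BASES4 <- c("A", "C", "G", "T")
AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")

#' Convert a Phred+33 quality string to integer scores
#'
#' @param qual Character scalar, Phred+33 encoded quality string.
#' @return Integer vector of per-base quality scores.
#' @export
phred_to_int <- function(qual) {
  if (is.na(qual) || !nzchar(qual)) return(integer(0))
  as.integer(charToRaw(qual)) - 33L
}

#' Convert integer quality scores to a Phred+33 string
#'
#' @param q Integer vector of Phred scores (each >= 0).
#' @return Character scalar.
#' @export
int_to_phred <- function(q) {
  if (length(q) == 0) return("")
  if (any(q < 0)) stop("Phred scores must be non-negative")
  rawToChar(as.raw(as.integer(q) + 33L))
}

#' Reverse-complement a nucleotide string
#' @param nt Character scalar over A/C/G/T/N.
#' @return Character scalar.
#' @export
revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# Translate a nucleotide string codon-by-codon using the standard genetic code.
# Incomplete trailing codons are dropped; codons containing characters outside
# A/C/G/T (e.g. N) translate to "X".
translate_nt <- function(nt) {
  n <- nchar(nt)
  if (n < 3) return("")
  n <- n - n %% 3L
  codons <- substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# deterministic seeded evaluation that does not disturb the caller's RNG
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# strip the allele suffix ("IGHV1-2*02" -> "IGHV1-2")
#' Strip the allele suffix from an allele name
#' @param allele Character vector of allele names such as `"IGHV1-2*02"`.
#' @return Gene-level names with the `*NN` suffix removed.
#' @export
gene_of <- function(allele) sub("\\*.*$", "", allele)

# format a double so that as.numeric(format) round-trips exactly
num_to_chr <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- as.numeric(s) != x
  s[bad] <- sprintf("%.17g", x[bad])
  s
}
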