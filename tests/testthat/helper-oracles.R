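# Shared fixtures and independent oracle implementations used by the suite.
# Oracles are deliberately written as naive re-implementations (matrix DP,
# exhaustive scans, regex) so they stay independent of the package's code
# paths.

toy_germline <- local({
  cache <- new.env()
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) cache[[key]] <- make_toy_germline(seed)
    cache[[key]]
  }
})

# Wagner-Fischer edit distance (full quadratic DP, iterative matrix)
oracle_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n; D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- min(D[i, j] + (x[i] != y[j]),
                             D[i, j + 1] + 1L, D[i + 1, j] + 1L)
    }
  }
  D[n + 1, m + 1]
}

oracle_identity <- function(a, b) {
  1 - oracle_levenshtein(a, b) / max(nchar(a), nchar(b))
}

# order-respecting greedy clustering, re-implemented naively
oracle_greedy_cluster <- function(records, threshold) {
  ord <- order(-records$abundance, -nchar(records$nt), records$nt)
  cl <- integer(nrow(records))
  centroids <- integer(0)  # row indices of founders, in founding order
  for (k in ord) {
    assigned <- FALSE
    for (ci in seq_along(centroids)) {
      if (oracle_identity(records$nt[k], records$nt[centroids[ci]]) >= threshold) {
        cl[k] <- ci; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      centroids <- c(centroids, k)
      cl[k] <- length(centroids)
    }
  }
  cl
}

# sequon scan via lookahead regex
oracle_sequons <- function(aa) {
  m <- gregexpr("N(?=[^P][ST])", aa, perl = TRUE)[[1]]
  if (m[1] < 0) integer(0) else as.integer(m)
}

random_aa <- function(n, alphabet = c("A","C","D","E","F","G","H","I","K","L",
                                      "M","N","P","Q","R","S","T","V","W","Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")

# deterministic small UMI-free record table
records_of <- function(nt, abundance = 1L, umi = NA_character_) {
  new_records(read_id = sprintf("r%03d", seq_along(nt)), nt = nt,
              umi = umi, abundance = abundance)
}
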