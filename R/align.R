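# Pairwise alignment layer.  Germline assignment, isotype calling, and
# sequence search all use local (Smith-Waterman) alignment through
# Biostrings::pairwiseAlignment with nucleotide-BLAST-like scoring:
# match +2, mismatch -3, gap open 5, gap extend 2.  Significance is summarised
# by a Karlin-Altschul style statistic evalue_like = K * m * n * exp(-lambda*S)
# with K = 0.41, lambda = 0.625 (documented constants, configurable).

.ALN_DEFAULTS <- list(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2,
                      K = 0.41, lambda = 0.625)

aln_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = .ALN_DEFAULTS$match, mismatch = .ALN_DEFAULTS$mismatch,
        baseOnly = FALSE)
    }
    cache
  }
})

#' BLAST-like expectation statistic for an alignment score
#'
#' `K * m * n * exp(-lambda * S)`: monotone decreasing in the score `S` at
#' fixed search-space size `m * n`.
#'
#' @param score Alignment score.
#' @param m,n Lengths of the two sequences (search-space dimensions).
#' @param K,lambda Karlin-Altschul constants.
#' @return Positive real.
#' @export
evalue_like <- function(score, m, n, K = .ALN_DEFAULTS$K,
                        lambda = .ALN_DEFAULTS$lambda) {
  K * m * n * exp(-lambda * score)
}

# One pairwiseAlignment call for a set of references against one sequence
# (amortises the per-call overhead over all alleles of a segment class).
align_set <- function(refs, seq, type = "local") {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(refs),
    subject = Biostrings::DNAString(seq),
    type = type, substitutionMatrix = aln_submat(),
    gapOpening = .ALN_DEFAULTS$gap_open, gapExtension = .ALN_DEFAULTS$gap_extend)
}

# Materialise element `i` of an align_set() result as an "abrep_aln" list:
# score, 1-based inclusive spans in each sequence's own coordinates, identity
# over aligned columns (gaps and N excluded), per-column position maps,
# mismatch table and evalue_like.
aln_result <- function(obj, i, ref_len, seq_len) {
  a <- obj[i]
  pa <- chars(as.character(Biostrings::pattern(a)))
  sa <- chars(as.character(Biostrings::subject(a)))
  r0 <- Biostrings::start(Biostrings::pattern(a)) - 1L
  q0 <- Biostrings::start(Biostrings::subject(a)) - 1L
  ref_pos <- ifelse(pa == "-", NA_integer_, r0 + cumsum(pa != "-"))
  qry_pos <- ifelse(sa == "-", NA_integer_, q0 + cumsum(sa != "-"))
  both <- !is.na(ref_pos) & !is.na(qry_pos)
  informative <- both & pa != "N" & sa != "N"
  matches <- informative & pa == sa
  mism <- informative & pa != sa
  score <- Biostrings::score(obj)[i]
  res <- list(
    score = score,
    r_start = r0 + 1L, r_end = max(ref_pos, na.rm = TRUE),
    q_start = q0 + 1L, q_end = max(qry_pos, na.rm = TRUE),
    n_cols = sum(both), n_match = sum(matches), n_mismatch = sum(mism),
    n_informative = sum(informative),
    identity = if (sum(informative)) sum(matches) / sum(informative) else 0,
    ref_pos = ref_pos, qry_pos = qry_pos, ref_char = pa, qry_char = sa,
    mismatches = data.frame(ref_pos = ref_pos[mism], qry_base = sa[mism],
                            stringsAsFactors = FALSE),
    evalue = evalue_like(score, ref_len, seq_len))
  class(res) <- "abrep_aln"
  res
}

# single-reference convenience wrapper
align_local <- function(ref, seq, type = "local") {
  obj <- align_set(ref, seq, type = type)
  aln_result(obj, 1L, nchar(ref), nchar(seq))
}

# Best-scoring reference in a set: ties broken by identity (descending), then
# by name (lexicographic).  Returns NULL if the best score is below
# `min_score`, else list(index, aln).
align_best <- function(refs, names, seq, min_score = -Inf, type = "local") {
  obj <- align_set(refs, seq, type = type)
  sc <- Biostrings::score(obj)
  if (max(sc) < min_score) return(NULL)
  top <- which(sc == max(sc))
  if (length(top) == 1L) {
    i <- top
    aln <- aln_result(obj, i, nchar(refs[i]), nchar(seq))
  } else {
    alns <- lapply(top, function(i) aln_result(obj, i, nchar(refs[i]), nchar(seq)))
    ident <- vapply(alns, `[[`, numeric(1), "identity")
    k <- order(-ident, names[top])[1]
    i <- top[k]; aln <- alns[[k]]
  }
  list(index = i, aln = aln)
}

# offset the query coordinates of an alignment computed on a subsequence
shift_query <- function(a, offset) {
  a$q_start <- a$q_start + offset; a$q_end <- a$q_end + offset
  a$qry_pos <- a$qry_pos + offset
  a
}

# query position aligned to a given reference position (NA if gapped/absent)
query_pos_of <- function(a, ref_pos) {
  i <- match(ref_pos, a$ref_pos)
  if (is.na(i)) NA_integer_ else a$qry_pos[i]
}

# longest run of consecutive exactly-matching columns
longest_match_run <- function(a) {
  m <- !is.na(a$ref_pos) & !is.na(a$qry_pos) & a$ref_char == a$qry_char
  if (!any(m)) return(0L)
  r <- rle(m)
  max(r$lengths[r$values])
}
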