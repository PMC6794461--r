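# Signature-prevalence search (CDR3 motifs, numbered-position motifs,
# sequence similarity), signature frequencies, paired-chain prevalence, and
# rarefaction with the coefficient-of-variation statistic.

#' Compile a signature motif to an anchored regular expression
#'
#' Motif grammar: dash-separated residue slots as printed in repertoire
#' signature definitions; `"X"` matches any of the 20 amino acids, `"[...]"`
#' is a residue class, and a single letter is literal.
#'
#' @param motif Motif text, e.g. `"X-X-[AFILMYWV]-[EQ]-X"`.
#' @return Anchored regex (character scalar) with attribute `n_slots`.
#' @export
compile_motif <- function(motif) {
  slots <- strsplit(motif, "-", fixed = TRUE)[[1]]
  if (length(slots) == 0 || any(!nzchar(slots)))
    stop("malformed motif (empty slot) in: ", motif)
  aa_class <- paste(AA20, collapse = "")
  parts <- vapply(seq_along(slots), function(i) {
    s <- slots[i]
    if (s == "X") return(paste0("[", aa_class, "]"))
    if (grepl("^\\[[A-Z]+\\]$", s)) {
      residues <- chars(gsub("\\[|\\]", "", s))
      if (!all(residues %in% AA20))
        stop("motif slot ", i, " contains a non-amino-acid residue: ", s)
      return(s)
    }
    if (grepl("^[A-Z]$", s) && s %in% AA20) return(s)
    stop("malformed motif at slot ", i, ": '", s, "'")
  }, character(1))
  structure(paste0("^", paste(parts, collapse = ""), "$"),
            n_slots = length(slots))
}

#' Construct a signature query
#'
#' @param mode `"cdr3"` (CDR3 motif), `"position"` (numbered-position
#'   constraints) or `"sequence"` (similarity search).
#' @param motif CDR3 motif text (cdr3 mode).
#' @param positions `data.frame(scheme, position, residues)` (position mode);
#'   `residues` is a string of allowed amino acids.
#' @param query_seq Nucleotide query (sequence mode).
#' @param gene Optional gene- or allele-level V constraint.
#' @param isotype Optional isotype constraint.
#' @param cdr3_length Optional CDR3 amino-acid length constraint.
#' @return List of class `abrep_query`.
#' @export
signature_query <- function(mode = c("cdr3", "position", "sequence"),
                            motif = NULL, positions = NULL, query_seq = NULL,
                            gene = NULL, isotype = NULL, cdr3_length = NULL) {
  mode <- match.arg(mode)
  q <- list(mode = mode, gene = gene, isotype = isotype,
            cdr3_length = cdr3_length)
  if (mode == "cdr3") {
    if (is.null(motif)) stop("cdr3 mode requires a motif")
    q$motif <- motif
    q$regex <- compile_motif(motif)
  } else if (mode == "position") {
    if (is.null(positions) || nrow(positions) == 0)
      stop("position mode requires position constraints")
    q$positions <- positions
  } else {
    if (is.null(query_seq) || !nzchar(query_seq))
      stop("sequence mode requires a non-empty query sequence")
    q$query_seq <- query_seq
  }
  class(q) <- "abrep_query"
  q
}

# gene/allele constraint: allele-level ("*" present) compares full allele
# names, gene-level compares allele-stripped names
gene_matches <- function(constraint, v_call) {
  if (is.null(constraint)) return(rep(TRUE, length(v_call)))
  ok <- if (grepl("*", constraint, fixed = TRUE)) v_call == constraint
        else gene_of(v_call) == constraint
  ok & !is.na(v_call)
}

#' Match a CDR3-motif query against transcripts
#'
#' @param query `abrep_query` with `mode = "cdr3"`.
#' @param transcripts Annotated transcript table.
#' @return Logical vector: gene/isotype/length constraints hold and the CDR3
#'   amino-acid sequence matches the motif anchored over its full length.
#' @export
match_cdr3 <- function(query, transcripts) {
  stopifnot(query$mode == "cdr3")
  ok <- gene_matches(query$gene, transcripts$v_call)
  if (!is.null(query$isotype)) ok <- ok & transcripts$isotype == query$isotype
  if (!is.null(query$cdr3_length))
    ok <- ok & !is.na(transcripts$cdr3_aa) &
      nchar(transcripts$cdr3_aa) == query$cdr3_length
  hit <- !is.na(transcripts$cdr3_aa) & grepl(query$regex, transcripts$cdr3_aa)
  ok & hit
}

#' Match a numbered-position query against transcripts
#'
#' Every (scheme, position, residue-class) constraint must be satisfied;
#' positions that are unnumbered or unobserved in a transcript fail the
#' constraint.
#'
#' @param query `abrep_query` with `mode = "position"`.
#' @param transcripts Annotated transcript table (with the `numbering`
#'   list-column).
#' @return Logical vector.
#' @export
match_position <- function(query, transcripts) {
  stopifnot(query$mode == "position")
  ok <- gene_matches(query$gene, transcripts$v_call)
  if (!is.null(query$isotype)) ok <- ok & transcripts$isotype == query$isotype
  for (k in seq_len(nrow(query$positions))) {
    scheme <- query$positions$scheme[k]
    pos <- as.character(query$positions$position[k])
    allowed <- chars(query$positions$residues[k])
    ok <- ok & vapply(transcripts$numbering, function(num) {
      if (is.null(num) || is.null(num[[scheme]])) return(FALSE)
      i <- match(pos, num[[scheme]]$position)
      !is.na(i) && num[[scheme]]$residue[i] %in% allowed
    }, logical(1))
  }
  ok
}

#' Similarity search of a query sequence against transcripts
#'
#' Local alignment of the query against every transcript; matches are
#' transcripts with expectation statistic below `evalue_max`, ranked by
#' alignment score.
#'
#' @param query `abrep_query` with `mode = "sequence"`.
#' @param transcripts Annotated transcript table.
#' @param evalue_max Significance threshold (default 1e-6).
#' @return The matched transcript rows, ranked by decreasing score, with
#'   `match_score` and `match_evalue` columns.
#' @export
match_sequence <- function(query, transcripts, evalue_max = 1e-6) {
  stopifnot(query$mode == "sequence")
  # local alignment is symmetric in score: batch with transcripts as patterns
  obj <- align_set(transcripts$nt, query$query_seq)
  score <- Biostrings::score(obj)
  ev <- evalue_like(score, nchar(transcripts$nt), nchar(query$query_seq))
  ok <- if (is.null(query$gene)) rep(TRUE, nrow(transcripts))
        else gene_matches(query$gene, transcripts$v_call)
  keep <- which(ev < evalue_max & ok)
  keep <- keep[order(-score[keep])]
  out <- transcripts[keep, , drop = FALSE]
  out$match_score <- score[keep]
  out$match_evalue <- ev[keep]
  out
}

#' Signature frequency in one repertoire
#'
#' Frequency = matched transcripts / denominator, where the denominator is
#' the number of unique transcripts assigned to the query's germline gene (or
#' allele) when a gene constraint is present and `denominator = "gene"`, and
#' the whole repertoire otherwise.
#'
#' @param query `abrep_query`.
#' @param transcripts Curated unique transcripts of one repertoire.
#' @param denominator `"gene"` or `"all"`; the default uses `"gene"` when the
#'   query has a gene constraint, `"all"` otherwise.
#' @param evalue_max Threshold for sequence mode.
#' @return One-row `data.frame(n_matched, n_denominator, frequency)`;
#'   `frequency` is `NA` (absent, not 0) when the denominator is zero.
#' @export
signature_frequency <- function(query, transcripts,
                                denominator = NULL, evalue_max = 1e-6) {
  denominator <- denominator %||%
    (if (!is.null(query$gene)) "gene" else "all")
  denominator <- match.arg(denominator, c("gene", "all"))
  matched <- switch(query$mode,
    cdr3 = sum(match_cdr3(query, transcripts)),
    position = sum(match_position(query, transcripts)),
    sequence = nrow(match_sequence(query, transcripts, evalue_max)))
  denom <- if (denominator == "gene" && !is.null(query$gene))
    sum(gene_matches(query$gene, transcripts$v_call)) else nrow(transcripts)
  data.frame(n_matched = matched, n_denominator = denom,
             frequency = if (denom > 0) matched / denom else NA_real_)
}

#' Aggregate per-repertoire signature frequencies
#'
#' @param query `abrep_query`.
#' @param repertoires Named list of unique-transcript tables.
#' @param ... Passed to [signature_frequency()].
#' @return List of class `abrep_prevalence`: `per_repertoire` (one row per
#'   repertoire) and `aggregate` (mean and sd of frequencies, fraction of
#'   repertoires with at least one match).
#' @export
signature_prevalence <- function(query, repertoires, ...) {
  rows <- do.call(rbind, lapply(repertoires, signature_frequency,
                                query = query, ...))
  rows$repertoire_id <- names(repertoires) %||%
    sprintf("rep%d", seq_along(repertoires))
  f <- rows$frequency[!is.na(rows$frequency)]
  structure(list(per_repertoire = rows,
                 aggregate = data.frame(
                   mean_frequency = mean(f), sd_frequency = sd(f),
                   fraction_positive = mean(rows$n_matched > 0))),
            class = "abrep_prevalence")
}

#' Paired heavy/light prevalence under random pairing
#'
#' Assuming random pairing of heavy and light chains, the prevalence of
#' antibodies carrying both signatures is the product of the two
#' whole-repertoire frequencies, reported per million B cells to two
#' significant figures.
#'
#' @param heavy_freq,light_freq Signature frequencies in `[0, 1]`, on the
#'   same (whole-repertoire) denominator convention.
#' @return Paired prevalence per million B cells (2 significant figures).
#' @export
pairing_frequency <- function(heavy_freq, light_freq) {
  if (heavy_freq < 0 || heavy_freq > 1 || light_freq < 0 || light_freq > 1)
    stop("frequencies must be in [0, 1]")
  signif(heavy_freq * light_freq * 1e6, 2)
}

#' Rarefaction of a signature frequency with coefficient of variation
#'
#' For each sampling size `i`, draws `n_repeats` random subsets of `i`
#' repertoires without replacement (independently across repeats), computes
#' the mean per-repertoire frequency of each repeat, and summarises the
#' repeat means by their coefficient of variation
#' `CV_i = sd(means) / mean(means)` (sample sd, n-1 denominator).
#'
#' @param freqs Per-repertoire signature frequencies, or an
#'   `abrep_prevalence` object.
#' @param sizes Sampling sizes (each at most `length(freqs)`).
#' @param n_repeats Repeats per size (default 20).
#' @param seed Integer seed.
#' @param exhaustive If `TRUE`, enumerate all subsets of each size instead of
#'   sampling (sizes must keep `choose(n, i)` manageable).
#' @return `data.frame` of class `abrep_rarefaction`: `size`, `n_repeats`,
#'   `mean_freq`, `cv`.
#' @export
rarefaction_cv <- function(freqs, sizes, n_repeats = 20, seed = 1,
                           exhaustive = FALSE) {
  if (inherits(freqs, "abrep_prevalence"))
    freqs <- freqs$per_repertoire$frequency
  n <- length(freqs)
  if (any(sizes > n)) stop("sampling size exceeds the number of repertoires")
  if (any(sizes < 1)) stop("sampling sizes must be >= 1")
  rows <- with_seed(seed, lapply(sizes, function(i) {
    means <- if (exhaustive) {
      apply(combn(n, i), 2, function(ix) mean(freqs[ix]))
    } else {
      vapply(seq_len(n_repeats),
             function(r) mean(freqs[sample(n, i)]), numeric(1))
    }
    m <- mean(means)
    cv <- if (length(means) > 1 && m != 0) sd(means) / m else 0
    data.frame(size = i, n_repeats = length(means), mean_freq = m, cv = cv)
  }))
  out <- do.call(rbind, rows)
  class(out) <- c("abrep_rarefaction", "data.frame")
  out
}
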