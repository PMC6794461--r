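# Read-to-transcript annotation: pair merging, quality filtering, germline
# V/(D)/J assignment, CDR3 junction extraction, isotype calling,
# hypermutation quantification and antibody position numbering.

#' Quality-control thresholds
#'
#' @param max_expected_miscalls Maximum sum of per-base error probabilities
#'   (expected miscalls) tolerated per transcript (default 20).
#' @param min_merged_length Minimum merged transcript length in nt
#'   (default 300).
#' @param isotype_evalue_max Maximum expectation statistic for an isotype
#'   (CH1) assignment (default 1e-6).
#' @return List of class `abrep_qc`.
#' @export
qc_thresholds <- function(max_expected_miscalls = 20, min_merged_length = 300,
                          isotype_evalue_max = 1e-6) {
  if (max_expected_miscalls <= 0 || min_merged_length <= 0 || isotype_evalue_max <= 0)
    stop("all QC thresholds must be positive")
  structure(list(max_expected_miscalls = max_expected_miscalls,
                 min_merged_length = min_merged_length,
                 isotype_evalue_max = isotype_evalue_max), class = "abrep_qc")
}

#' Expected number of miscalls from Phred qualities
#'
#' Sum of per-base error probabilities `10^(-Q/10)`.
#'
#' @param quals Integer vector of Phred scores, or a Phred+33 string.
#' @return Expected error count (real).
#' @export
expected_errors <- function(quals) {
  if (is.character(quals)) quals <- phred_to_int(quals)
  if (length(quals) == 0) stop("empty quality vector")
  if (any(quals < 0)) stop("negative Phred score")
  sum(10^(-quals / 10))
}

#' Merge a read pair by its best ungapped overlap
#'
#' The mate is reverse-complemented, all overlap offsets of at least
#' `min_overlap` bases are scanned, and the overlap maximising matches minus
#' mismatches is taken (ties: longer overlap), so a clean partial overlap is
#' preferred over a longer noisy one.  Disagreeing overlap bases are resolved in
#' favour of the higher Phred score; merged qualities are the maximum of the
#' two on agreement and the difference of the two on disagreement.  Pairs
#' whose best overlap has identity < 0.8 are rejected.
#'
#' @param r1,r2 Single records (one-row data.frames or lists with `nt`,
#'   `qual`); `r2` is the mate to be reverse-complemented.
#' @param min_overlap Minimum overlap length (default 10).
#' @return List with `record` (merged single-row record table, or `NULL`) and
#'   `reason` (`NA` on success; `"too_short"`, `"no_overlap"` or
#'   `"low_identity"` on rejection).
#' @export
merge_read_pair <- function(r1, r2, min_overlap = 10) {
  n1 <- nchar(r1$nt); n2 <- nchar(r2$nt)
  if (n1 < min_overlap || n2 < min_overlap)
    return(list(record = NULL, reason = "too_short"))
  s2 <- revcomp(r2$nt)
  q1 <- phred_to_int(r1$qual %||% NA_character_)
  q2 <- rev(phred_to_int(r2$qual %||% NA_character_))
  if (length(q1) == 0) q1 <- rep(30L, n1)
  if (length(q2) == 0) q2 <- rep(30L, n2)
  a <- chars(r1$nt); b <- chars(s2)
  best_o <- 0L; best_m <- 0L; best_s <- -Inf
  for (o in seq(min_overlap, min(n1, n2))) {
    m <- sum(a[(n1 - o + 1):n1] == b[1:o])
    s <- m - (o - m)
    if (s >= best_s) { best_s <- s; best_m <- m; best_o <- o }
  }
  if (best_o == 0L) return(list(record = NULL, reason = "no_overlap"))
  if (best_m / best_o < 0.8) return(list(record = NULL, reason = "low_identity"))
  i1 <- (n1 - best_o + 1):n1; i2 <- 1:best_o
  agree <- a[i1] == b[i2]
  use1 <- agree | q1[i1] >= q2[i2]
  ov_nt <- ifelse(use1, a[i1], b[i2])
  ov_q <- ifelse(agree, pmax(q1[i1], q2[i2]), abs(q1[i1] - q2[i2]))
  nt <- paste(c(a[seq_len(n1 - best_o)], ov_nt, b[-seq_len(best_o)]), collapse = "")
  qual <- int_to_phred(c(q1[seq_len(n1 - best_o)], ov_q, q2[-seq_len(best_o)]))
  rec <- new_records(read_id = r1$read_id %||% "merged", nt = nt, qual = qual,
                     umi = r1$umi %||% NA_character_)
  list(record = rec, reason = NA_character_, overlap = best_o, matches = best_m)
}

#' Filter merged records on length and expected miscalls
#'
#' Records shorter than `min_merged_length` nt or with more than
#' `max_expected_miscalls` expected miscalls are dropped, with the reason
#' recorded per read.  Records without qualities (FASTA input) are only
#' subject to the length filter.
#'
#' @param records A record table.
#' @param thresholds An [qc_thresholds()] object.
#' @return List with `kept` (record table) and `rejected` (record table with
#'   an extra `reason` column).
#' @export
qc_filter <- function(records, thresholds = qc_thresholds()) {
  len <- nchar(records$nt)
  ee <- vapply(records$qual, function(q)
    if (is.na(q)) 0 else expected_errors(q), numeric(1), USE.NAMES = FALSE)
  reason <- rep(NA_character_, nrow(records))
  reason[ee > thresholds$max_expected_miscalls] <- "expected_errors"
  reason[len < thresholds$min_merged_length] <- "length"
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  list(kept = records[is.na(reason), , drop = FALSE], rejected = rejected)
}

#' Assign germline V, D and J genes to a read
#'
#' The V call is the highest-scoring local alignment among V alleles
#' (ties broken by higher identity, then lexicographic allele name); the J is
#' searched 3' of the V span; the D (heavy chain only) is searched between V
#' and J and the call is withheld unless the best D alignment contains at
#' least `d_min_match` contiguous matching nt.
#'
#' @param record Single record (list or one-row data.frame with `nt`).
#' @param germline `abrep_germline` reference.
#' @param chain Restrict to one chain, or `NULL` to infer from the best V.
#' @param min_v_score,min_j_score Minimum alignment scores below which the
#'   transcript is marked unassignable.
#' @param d_min_match Minimum contiguous matching nt for a D call (default 5).
#' @return List with `v_call`, `d_call`, `j_call`, `chain`, and alignment
#'   results `v`, `d`, `j`; or, when unassignable, `v_call = NA` plus a
#'   `reason`.
#' @export
assign_vdj <- function(record, germline, chain = NULL,
                       min_v_score = 50, min_j_score = 20, d_min_match = 5) {
  nt <- record$nt
  vs <- germline_subset(germline, "V", chain)
  if (nrow(vs) == 0) stop("no V segments in germline reference")
  vb <- align_best(vs$ungapped_nt, vs$allele_name, nt, min_score = min_v_score)
  if (is.null(vb))
    return(list(v_call = NA_character_, d_call = NA_character_,
                j_call = NA_character_, reason = "no_v_match"))
  v_res <- vb$aln
  v_call <- vs$allele_name[vb$index]
  v_chain <- vs$chain[vb$index]

  js <- germline_subset(germline, "J", v_chain)
  j_off <- v_res$q_end
  tail_nt <- if (j_off < nchar(nt)) substr(nt, j_off + 1, nchar(nt)) else ""
  if (nrow(js) == 0 || nchar(tail_nt) < 6)
    return(list(v_call = v_call, d_call = NA_character_,
                j_call = NA_character_, v = v_res, reason = "no_j_match"))
  jb <- align_best(js$ungapped_nt, js$allele_name, tail_nt,
                   min_score = min_j_score)
  if (is.null(jb))
    return(list(v_call = v_call, d_call = NA_character_,
                j_call = NA_character_, v = v_res, reason = "no_j_match"))
  j_res <- shift_query(jb$aln, j_off)
  j_call <- js$allele_name[jb$index]

  d_call <- NA_character_; d_res <- NULL
  if (v_chain == "heavy") {
    ds <- germline_subset(germline, "D", "heavy")
    mid_s <- v_res$q_end + 1L; mid_e <- j_res$q_start - 1L
    if (nrow(ds) > 0 && mid_e - mid_s + 1 >= d_min_match) {
      mid <- substr(nt, mid_s, mid_e)
      db <- align_best(ds$ungapped_nt, ds$allele_name, mid)
      if (!is.null(db) && longest_match_run(db$aln) >= d_min_match) {
        d_call <- ds$allele_name[db$index]
        d_res <- shift_query(db$aln, mid_s - 1L)
      }
    }
  }
  list(v_call = v_call, d_call = d_call, j_call = j_call, chain = v_chain,
       v = v_res, d = d_res, j = j_res)
}

#' Extract the CDR3 junction from an annotated read
#'
#' Locates the codon aligned to the germline V's conserved 2nd Cys (IMGT
#' position 104) and the first W (heavy, WGXG) or F (light, FGXG) anchor of
#' the J region (IMGT 118) in the V reading frame; the CDR3 is everything
#' strictly between them (IMGT 105-117 convention).
#'
#' @param nt Transcript sequence.
#' @param v_res,j_res Alignment results from [assign_vdj()].
#' @param germ_v Germline row of the assigned V allele.
#' @param chain `"heavy"`, `"kappa"` or `"lambda"`.
#' @return List `cdr3_nt`, `cdr3_aa`, `cys_q` (nt position of the Cys codon),
#'   `w_q` (nt position of the anchor codon); or `NULL` when either anchor is
#'   unlocatable or the interval is not a multiple of 3.
#' @export
extract_cdr3 <- function(nt, v_res, j_res, germ_v, chain = "heavy") {
  cys <- germ_v$cys104_start
  if (is.na(cys)) cys <- nchar(germ_v$ungapped_nt) - 2L
  q <- vapply(cys:(cys + 2L), function(p) query_pos_of(v_res, p) %||% NA_integer_,
              integer(1))
  if (any(is.na(q)) || q[2] != q[1] + 1L || q[3] != q[1] + 2L) return(NULL)
  cys_q <- q[1]
  if (translate_nt(substr(nt, cys_q, cys_q + 2L)) != "C") return(NULL)
  aa <- translate_nt(substr(nt, cys_q, nchar(nt)))
  pat <- if (chain == "heavy") "WG.G" else "FG.G"
  hits <- gregexpr(pat, aa)[[1]]
  if (hits[1] < 0) return(NULL)
  hits <- hits[hits > 1]  # anchor must lie strictly after the Cys
  for (k in hits) {
    w_q <- cys_q + 3L * (k - 1L)
    if (!is.null(j_res) &&
        (w_q < j_res$q_start - 3L || w_q > j_res$q_end)) next
    cdr3_nt <- substr(nt, cys_q + 3L, w_q - 1L)
    if (nchar(cdr3_nt) %% 3 != 0 || nchar(cdr3_nt) < 3) next
    return(list(cdr3_nt = cdr3_nt, cdr3_aa = translate_nt(cdr3_nt),
                cys_q = cys_q, w_q = w_q))
  }
  NULL
}

ISOTYPE_OF <- c(M = "IgM", D = "IgD", G = "IgG", A = "IgA", E = "IgE")

#' Assign the isotype of a heavy-chain transcript
#'
#' The 3' terminus of the transcript is aligned against the constant-domain-1
#' (CH1) entries of the reference; the best hit with expectation statistic at
#' or below `evalue_max` determines the isotype, otherwise `"unknown"`.
#'
#' @param nt Transcript sequence.
#' @param germline `abrep_germline` reference containing C entries.
#' @param after Search only 3' of this position (typically the J span end);
#'   `NULL` searches the final 120 nt.
#' @param evalue_max Significance threshold (default 1e-6).
#' @return Isotype string (`"IgM"`, `"IgG"`, ... or `"unknown"`).
#' @export
assign_isotype <- function(nt, germline, after = NULL, evalue_max = 1e-6) {
  cs <- germline_subset(germline, "C", "heavy")
  if (nrow(cs) == 0) return("unknown")
  start <- if (!is.null(after)) after + 1L else max(1L, nchar(nt) - 119L)
  if (start > nchar(nt) - 9L) return("unknown")
  tail_nt <- substr(nt, start, nchar(nt))
  obj <- align_set(cs$ungapped_nt, tail_nt)
  evs <- evalue_like(Biostrings::score(obj), nchar(cs$ungapped_nt),
                     nchar(tail_nt))
  best <- which.min(evs)
  if (evs[best] > evalue_max) return("unknown")
  iso <- ISOTYPE_OF[substr(cs$allele_name[best], 4, 4)]
  if (is.na(iso)) "unknown" else unname(iso)
}

#' Productivity check (frame shifts and stop codons)
#'
#' The reading frame is inherited from the germline V; a transcript is
#' productive iff the CDR3 anchors were located, the V alignment carries no
#' net out-of-frame insertion/deletion, and the V(D)J region contains no stop
#' codon.
#'
#' @param nt Transcript sequence.
#' @param v_res V alignment result.
#' @param cdr3 Result of [extract_cdr3()] (possibly `NULL`).
#' @param j_res J alignment result (used to bound the translated region).
#' @return Logical.
#' @export
detect_frameshift_stop <- function(nt, v_res, cdr3, j_res = NULL) {
  if (is.null(cdr3)) return(FALSE)
  n_ref_gap <- sum(is.na(v_res$ref_pos))
  n_qry_gap <- sum(is.na(v_res$qry_pos))
  if ((n_ref_gap - n_qry_gap) %% 3 != 0) return(FALSE)
  t_start <- cdr3$cys_q - 3L * floor((cdr3$cys_q - v_res$q_start) / 3)
  t_end <- if (!is.null(j_res)) j_res$q_end else nchar(nt)
  aa <- translate_nt(substr(nt, t_start, t_end))
  !grepl("*", aa, fixed = TRUE)
}

#' Somatic hypermutation level and amino-acid substitutions
#'
#' `shm_nt_pct` is 100 x mismatched columns / aligned V columns, with N bases
#' excluded from numerator and denominator.  Amino-acid substitutions are
#' reported per IMGT position for every fully aligned, gap-free, N-free
#' germline codon.
#'
#' @param v_res V alignment result.
#' @param germ_v Germline row of the assigned V allele.
#' @return List with `shm_nt_pct` and `shm_aa_subs`
#'   (`data.frame(imgt_pos, germline_aa, observed_aa)`).
#' @export
compute_shm <- function(v_res, germ_v) {
  pct <- if (v_res$n_informative > 0) 100 * v_res$n_mismatch / v_res$n_informative else 0
  aamap <- imgt_aa_pos(germ_v)
  vlen <- nchar(germ_v$ungapped_nt)
  subs <- list()
  first_codon <- ceiling(v_res$r_start / 3) - 1L
  for (a in seq.int(max(1L, first_codon), vlen %/% 3)) {
    rs <- 3L * (a - 1L) + 1L
    cols <- match(rs:(rs + 2L), v_res$ref_pos)
    if (any(is.na(cols))) next
    qp <- v_res$qry_pos[cols]
    if (any(is.na(qp)) || qp[3] != qp[1] + 2L) next
    rc <- v_res$ref_char[cols]; qc <- v_res$qry_char[cols]
    if (any(c(rc, qc) == "N")) next
    g_aa <- translate_nt(paste(rc, collapse = ""))
    o_aa <- translate_nt(paste(qc, collapse = ""))
    if (g_aa != o_aa) {
      subs[[length(subs) + 1L]] <- data.frame(
        imgt_pos = aamap[rs], germline_aa = g_aa, observed_aa = o_aa,
        stringsAsFactors = FALSE)
    }
  }
  shm_aa_subs <- if (length(subs)) do.call(rbind, subs) else
    data.frame(imgt_pos = integer(0), germline_aa = character(0),
               observed_aa = character(0), stringsAsFactors = FALSE)
  list(shm_nt_pct = pct, shm_aa_subs = shm_aa_subs)
}

#' Static IMGT to Kabat/Chothia translation table
#'
#' Position-numbering translation shipped for the toy germline reference
#' (user-extensible: supply any `data.frame(imgt, kabat, chothia)` with IMGT
#' variable-domain positions 1..104).
#'
#' @return A `data.frame` with character columns `imgt`, `kabat`, `chothia`.
#' @export
default_numbering_table <- function() {
  kabat <- c(as.character(1:30), "31", "31A", "31B", as.character(32:62),
             "62A", as.character(63:101))
  chothia <- c(as.character(1:30), "30A", "30B", "30C", as.character(31:61),
               as.character(62:101))
  data.frame(imgt = as.character(1:104), kabat = kabat, chothia = chothia,
             stringsAsFactors = FALSE)
}

# IMGT CDR3 labels for a junction of L residues (between anchors 104 and 118):
# symmetric fill from 105 upward and 117 downward; insertions beyond 13
# residues get 111.x / 112.x codes.
imgt_cdr3_labels <- function(L) {
  if (L <= 13) {
    nl <- ceiling(L / 2); nr <- L - nl
    c(as.character(seq(105, length.out = nl)),
      if (nr > 0) as.character(seq(118 - nr, 117)) else character(0))
  } else {
    extra <- L - 13
    li <- ceiling(extra / 2); ri <- extra - li
    c(as.character(105:111),
      paste0("111.", seq_len(li)),
      if (ri > 0) paste0("112.", rev(seq_len(ri))) else character(0),
      as.character(112:117))
  }
}

#' Number antibody positions in a transcript
#'
#' IMGT numbering maps aligned V columns through the germline's gapped
#' coordinates; the CDR3 is numbered by the IMGT symmetric-fill rule between
#' anchors 104 and 118, and J-region residues continue from 118.  Kabat and
#' Chothia numberings are produced by composing the IMGT map with a static
#' translation table; positions absent from the table are unmapped and
#' dropped.
#'
#' @param nt Transcript sequence.
#' @param v_res V alignment result.
#' @param germ_v Germline row of the assigned V allele.
#' @param cdr3 Result of [extract_cdr3()] (may be `NULL`).
#' @param j_res J alignment result (may be `NULL`).
#' @param scheme `"imgt"`, `"kabat"` or `"chothia"`.
#' @param table Translation table, see [default_numbering_table()].
#' @return `data.frame(position, residue, aa_pos)` where `aa_pos` is the
#'   linear amino-acid index in the V reading frame.
#' @export
number_positions <- function(nt, v_res, germ_v, cdr3 = NULL, j_res = NULL,
                             scheme = c("imgt", "kabat", "chothia"),
                             table = default_numbering_table()) {
  scheme <- match.arg(scheme)
  aamap <- imgt_aa_pos(germ_v)
  vlen <- nchar(germ_v$ungapped_nt)
  lab <- character(0); res <- character(0); qstart <- integer(0)
  for (a in seq_len(vlen %/% 3)) {
    rs <- 3L * (a - 1L) + 1L
    cols <- match(rs:(rs + 2L), v_res$ref_pos)
    if (any(is.na(cols))) next
    qp <- v_res$qry_pos[cols]
    if (any(is.na(qp)) || qp[3] != qp[1] + 2L) next
    lab <- c(lab, as.character(aamap[rs]))
    res <- c(res, translate_nt(substr(nt, qp[1], qp[1] + 2L)))
    qstart <- c(qstart, qp[1])
  }
  if (!is.null(cdr3)) {
    L <- nchar(cdr3$cdr3_aa)
    if (L > 0) {
      lab <- c(lab, imgt_cdr3_labels(L))
      res <- c(res, chars(cdr3$cdr3_aa))
      qstart <- c(qstart, seq(cdr3$cys_q + 3L, by = 3L, length.out = L))
    }
    j_end <- if (!is.null(j_res)) j_res$q_end else nchar(nt)
    n_j <- max(0L, (j_end - cdr3$w_q + 1L) %/% 3)
    if (n_j > 0) {
      lab <- c(lab, as.character(seq(118, length.out = n_j)))
      jq <- seq(cdr3$w_q, by = 3L, length.out = n_j)
      res <- c(res, vapply(jq, function(p) translate_nt(substr(nt, p, p + 2L)),
                           character(1)))
      qstart <- c(qstart, jq)
    }
  }
  frame0 <- if (length(qstart)) min(qstart) else 1L
  out <- data.frame(position = lab, residue = res,
                    aa_pos = (qstart - frame0) %/% 3L + 1L,
                    stringsAsFactors = FALSE)
  if (scheme != "imgt") {
    idx <- match(out$position, table$imgt)
    out$position <- table[[scheme]][idx]
    out <- out[!is.na(out$position), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Annotate a set of records against a germline reference
#'
#' Runs V/(D)/J assignment, CDR3 extraction, isotype calling, productivity
#' check, hypermutation quantification and position numbering on every
#' record.
#'
#' @param records Record table (merged, QC-filtered reads).
#' @param germline `abrep_germline` reference.
#' @param chain Restrict germline search to one chain, or `NULL`.
#' @param repertoire_id,donor_id Metadata attached to every transcript.
#' @param schemes Numbering schemes to compute (IMGT always included).
#' @param ... Passed to [assign_vdj()].
#' @return A `data.frame` of class `abrep_annotated`: record columns plus
#'   `v_call`, `d_call`, `j_call`, `isotype`, `cdr3_nt`, `cdr3_aa`,
#'   `shm_nt_pct`, `v_identity`, `productive`, `repertoire_id`, `donor_id`
#'   and list-columns `shm_aa_subs` and `numbering`.
#' @export
annotate_repertoire <- function(records, germline, chain = NULL,
                                repertoire_id = "rep1", donor_id = "donor1",
                                schemes = c("imgt", "kabat", "chothia"), ...) {
  schemes <- union("imgt", schemes)
  n <- nrow(records)
  out <- records
  out$v_call <- out$d_call <- out$j_call <- NA_character_
  out$isotype <- "unknown"
  out$cdr3_nt <- out$cdr3_aa <- NA_character_
  out$shm_nt_pct <- NA_real_
  out$v_identity <- NA_real_
  out$productive <- FALSE
  out$repertoire_id <- repertoire_id
  out$donor_id <- donor_id
  out$shm_aa_subs <- rep(list(NULL), n)
  out$numbering <- rep(list(NULL), n)
  for (i in seq_len(n)) {
    vdj <- assign_vdj(records[i, ], germline, chain = chain, ...)
    if (is.na(vdj$v_call)) next
    out$v_call[i] <- vdj$v_call
    out$d_call[i] <- vdj$d_call
    out$j_call[i] <- vdj$j_call
    out$v_identity[i] <- vdj$v$identity
    germ_v <- germline_get(germline, vdj$v_call)
    nt <- records$nt[i]
    cdr3 <- if (!is.na(vdj$j_call))
      extract_cdr3(nt, vdj$v, vdj$j, germ_v, chain = vdj$chain) else NULL
    if (!is.null(cdr3)) {
      out$cdr3_nt[i] <- cdr3$cdr3_nt
      out$cdr3_aa[i] <- cdr3$cdr3_aa
    }
    if (identical(vdj$chain, "heavy")) {
      out$isotype[i] <- assign_isotype(nt, germline,
                                       after = if (!is.na(vdj$j_call)) vdj$j$q_end)
    }
    out$productive[i] <- detect_frameshift_stop(nt, vdj$v, cdr3, vdj$j)
    shm <- compute_shm(vdj$v, germ_v)
    out$shm_nt_pct[i] <- shm$shm_nt_pct
    out$shm_aa_subs[[i]] <- shm$shm_aa_subs
    out$numbering[[i]] <- setNames(lapply(schemes, function(s)
      number_positions(nt, vdj$v, germ_v, cdr3, vdj$j, scheme = s)), schemes)
  }
  class(out) <- c("abrep_annotated", "data.frame")
  out
}
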