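# Curation: collapse raw transcripts into a unique, error-suppressed dataset
# via the UMI-consensus or cluster-dedup path, then repertoire-level filters.

#' Curation parameters
#'
#' @param umi_subcluster_identity Identity threshold for clustering within a
#'   UMI group (default 0.97).
#' @param no_umi_cluster_identity Identity threshold for the non-UMI
#'   cluster-dedup path (default 0.99).
#' @param min_cluster_size Minimum total cluster size (reads) kept on the
#'   non-UMI path (default 2).
#' @param min_repertoire_unique Minimum unique transcripts for a repertoire to
#'   be retained (default 1700).
#' @return List of class `abrep_curation`.
#' @export
curation_params <- function(umi_subcluster_identity = 0.97,
                            no_umi_cluster_identity = 0.99,
                            min_cluster_size = 2,
                            min_repertoire_unique = 1700) {
  stopifnot(umi_subcluster_identity > 0, umi_subcluster_identity <= 1,
            no_umi_cluster_identity > 0, no_umi_cluster_identity <= 1,
            min_cluster_size >= 1, min_repertoire_unique >= 1)
  structure(list(umi_subcluster_identity = umi_subcluster_identity,
                 no_umi_cluster_identity = no_umi_cluster_identity,
                 min_cluster_size = as.integer(min_cluster_size),
                 min_repertoire_unique = as.integer(min_repertoire_unique)),
            class = "abrep_curation")
}

#' Pairwise nucleotide identity
#'
#' Identity of the optimal unit-cost global alignment: `1 - d / max(len)`
#' where `d` is the Levenshtein distance.  For equal-length substitution-only
#' pairs — the regime both clustering stages operate in — this equals matching
#' columns / aligned columns.  Symmetric; 1 for identical strings.
#'
#' @param a,b Non-empty nucleotide strings (vectorised over `b`).
#' @return Identity values in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (any(!nzchar(c(a, b)))) stop("empty sequence")
  d <- as.vector(utils::adist(a, b))
  1 - d / pmax(nchar(a), nchar(b))
}

# deterministic processing order for greedy clustering:
# abundance desc, length desc, sequence lexicographic
cluster_order <- function(records) {
  order(-records$abundance, -nchar(records$nt), records$nt)
}

#' Greedy centroid clustering at an identity threshold
#'
#' Records are processed in deterministic order (abundance descending, then
#' longer sequence, then lexicographic); each record joins the first existing
#' centroid with [pairwise_identity()] at or above the threshold, else founds
#' a new cluster.  The centroid is the founding record.  A length screen
#' (`|len_a - len_b| > (1-t) * max` implies identity < t) prunes impossible
#' candidates without changing the result.
#'
#' @param records Record table with `nt` and `abundance`.
#' @param identity_threshold Identity threshold in (0, 1].
#' @return The records (original row order) with an integer `cluster` column;
#'   attribute `"centroids"` holds, per cluster, the row index (into the
#'   returned table) of the founding record.
#' @export
greedy_cluster <- function(records, identity_threshold) {
  n <- nrow(records)
  ord <- cluster_order(records)
  seqs <- records$nt[ord]
  lens <- nchar(seqs)
  cl <- integer(n)
  cent_seq <- character(0); cent_len <- integer(0); cent_row <- integer(0)
  chunk <- 8L
  t <- identity_threshold
  for (k in seq_len(n)) {
    s <- seqs[k]; L <- lens[k]
    hit <- 0L
    if (length(cent_seq) > 0) {
      maxlen <- pmax(L, cent_len)
      cand <- which(abs(L - cent_len) <= (1 - t) * maxlen)
      if (length(cand) > chunk) {
        # pigeonhole screen: identity >= t bounds the edit distance by
        # d <= L*(1-t)/t, so at least one of d+1 contiguous blocks of the
        # record must occur verbatim in any joinable centroid
        d <- floor(L * (1 - t) / t)
        bounds <- round(seq(0, L, length.out = d + 2))
        keep <- rep(FALSE, length(cand))
        for (b in seq_len(d + 1)) {
          if (bounds[b + 1] <= bounds[b]) next
          blk <- substr(s, bounds[b] + 1L, bounds[b + 1])
          keep <- keep | grepl(blk, cent_seq[cand], fixed = TRUE)
        }
        cand <- cand[keep]
      }
      ci <- 1L
      while (ci <= length(cand)) {
        idx <- cand[ci:min(ci + chunk - 1L, length(cand))]
        ident <- pairwise_identity(s, cent_seq[idx])
        ok <- which(ident >= t)
        if (length(ok)) { hit <- idx[ok[1]]; break }
        ci <- ci + chunk
      }
    }
    if (hit == 0L) {
      cent_seq <- c(cent_seq, s); cent_len <- c(cent_len, L)
      cent_row <- c(cent_row, ord[k])
      hit <- length(cent_seq)
    }
    cl[ord[k]] <- hit
  }
  records$cluster <- cl
  attr(records, "centroids") <- cent_row
  records
}

# Column-wise majority consensus of a subcluster (star alignment to the most
# abundant member).  `weights` is the read count behind each distinct member
# sequence.  Ties go to the centre's base; majority-gap columns are dropped.
consensus_of <- function(seqs, weights = rep(1L, length(seqs))) {
  centre <- seqs[1]
  if (length(seqs) == 1L) return(centre)
  if (all(nchar(seqs) == nchar(centre))) {
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  } else {
    mat <- t(vapply(seqs, function(s) {
      if (s == centre) return(chars(centre))
      a <- align_local(centre, s, type = "global")
      out <- rep("-", nchar(centre))
      ok <- !is.na(a$ref_pos) & !is.na(a$qry_pos)
      out[a$ref_pos[ok]] <- a$qry_char[ok]
      out
    }, character(nchar(centre))))
  }
  cons <- mat[1, ]
  # only columns where some member disagrees with the centre need a vote
  disagree <- which(colSums(mat != rep(mat[1, ], each = nrow(mat))) > 0)
  for (j in disagree) {
    tab <- tapply(weights, mat[, j], sum)
    top <- names(tab)[tab == max(tab)]
    cons[j] <- if (mat[1, j] %in% top) mat[1, j] else sort(top)[1]
  }
  paste(cons[cons != "-"], collapse = "")
}

#' UMI-consensus deduplication
#'
#' Reads are grouped by identical UMI; each group is clustered at
#' `umi_subcluster_identity` (UMI collisions and PCR crossover can place
#' molecules from different cells under one UMI); each subcluster yields a
#' column-wise majority consensus with abundance equal to the subcluster read
#' count.  Exact duplicates among consensus sequences (multiple mRNA
#' molecules of one cell) are then collapsed.  Singletons — consensus
#' sequences with neither UMI duplicates (subcluster of one read) nor
#' consensus duplicates — are removed.
#'
#' @param records Record table; every row must carry a UMI.
#' @param params [curation_params()].
#' @return List with `unique` (record table of consensus transcripts;
#'   `abundance` = total reads collapsed) and `dropped`
#'   (singleton consensus records with a `reason` column).
#' @export
umi_consensus <- function(records, params = curation_params()) {
  if (any(is.na(records$umi)))
    stop("records without UMI; use cluster_dedup_no_umi() for non-UMI data")
  groups <- split(seq_len(nrow(records)), records$umi)
  cons_nt <- character(0); cons_reads <- integer(0)
  for (g in groups) {
    seqs <- records$nt[g]; ab <- records$abundance[g]
    w <- tapply(ab, seqs, sum)
    if (length(w) == 1L) {  # fast path: all reads in the group identical
      cons_nt <- c(cons_nt, names(w))
      cons_reads <- c(cons_reads, as.integer(w))
      next
    }
    # deterministic order: weight desc, length desc, lexicographic
    useq <- names(w)[order(-as.integer(w), -nchar(names(w)), names(w))]
    uw <- as.integer(w[useq])
    sub <- greedy_cluster(
      data.frame(read_id = useq, nt = useq, abundance = uw,
                 stringsAsFactors = FALSE),
      params$umi_subcluster_identity)
    for (cid in unique(sub$cluster)) {
      m <- which(sub$cluster == cid)
      cons_nt <- c(cons_nt, consensus_of(sub$nt[m], sub$abundance[m]))
      cons_reads <- c(cons_reads, sum(sub$abundance[m]))
    }
  }
  cons <- data.frame(nt = cons_nt, n_reads = cons_reads,
                     stringsAsFactors = FALSE)
  # collapse exact duplicates among consensus sequences
  agg <- aggregate(list(n_reads = cons$n_reads), by = list(nt = cons$nt), sum)
  agg$n_molecules <- as.integer(table(cons$nt)[agg$nt])
  agg$max_reads <- as.integer(tapply(cons$n_reads, cons$nt, max)[agg$nt])
  # singleton: no UMI duplicates (every subcluster had one read) and no
  # consensus duplicates (one molecule)
  agg$singleton <- agg$n_molecules == 1L & agg$max_reads == 1L
  agg <- agg[order(-agg$n_reads, agg$nt), , drop = FALSE]
  mk <- function(a, reason = NULL) {
    out <- new_records(read_id = if (nrow(a)) sprintf("uniq%06d", seq_len(nrow(a)))
                       else character(0),
                       nt = a$nt, abundance = if (nrow(a)) a$n_reads else integer(0))
    if (!is.null(reason)) out$reason <- rep(reason, nrow(out))
    out
  }
  list(unique = mk(agg[!agg$singleton, , drop = FALSE]),
       dropped = mk(agg[agg$singleton, , drop = FALSE], reason = "singleton"))
}

#' Cluster-based deduplication for non-UMI data
#'
#' Exact duplicates are collapsed first (duplicate counting), then records are
#' greedily clustered at `no_umi_cluster_identity`; each cluster emits its
#' highest-abundance member with abundance equal to the cluster's total read
#' count, and clusters with fewer than `min_cluster_size` total reads are
#' dropped (low-quality read suppression).
#'
#' @param records Record table.
#' @param params [curation_params()].
#' @return List with `unique` (record table) and `dropped` (cluster
#'   representatives that failed the size filter, with `reason`).
#' @export
cluster_dedup_no_umi <- function(records, params = curation_params()) {
  agg <- aggregate(list(abundance = records$abundance),
                   by = list(nt = records$nt), FUN = sum)
  recs <- new_records(read_id = sprintf("seq%06d", seq_len(nrow(agg))),
                      nt = agg$nt, abundance = agg$abundance)
  recs <- greedy_cluster(recs, params$no_umi_cluster_identity)
  cent <- attr(recs, "centroids")
  tot <- tapply(recs$abundance, recs$cluster, sum)
  out <- recs[cent, , drop = FALSE]
  out$abundance <- as.integer(tot[as.character(out$cluster)])
  out <- out[order(-out$abundance, out$nt), , drop = FALSE]
  out$read_id <- sprintf("uniq%06d", seq_len(nrow(out)))
  out$cluster <- NULL
  keep <- out$abundance >= params$min_cluster_size
  dropped <- out[!keep, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "cluster_size"
  rownames(out) <- rownames(dropped) <- NULL
  list(unique = out[keep, , drop = FALSE], dropped = dropped)
}

#' Repertoire-level size filter
#'
#' A repertoire is dropped iff it contains fewer unique transcripts than
#' `min_repertoire_unique` (artifact and small-sample suppression).
#'
#' @param unique_records Curated unique-transcript table.
#' @param params [curation_params()].
#' @return List with `keep` (logical) and `n_unique`; the decision is also
#'   reported via `message()`.
#' @export
repertoire_filter <- function(unique_records, params = curation_params()) {
  n <- nrow(unique_records)
  keep <- n >= params$min_repertoire_unique
  message(sprintf("repertoire %s: %d unique transcripts (minimum %d)",
                  if (keep) "kept" else "dropped", n,
                  params$min_repertoire_unique))
  list(keep = keep, n_unique = n)
}
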