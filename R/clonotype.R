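# Clonotype clustering, gene-specific substitution profiles (GSSP) and
# mutation-rarity scoring.

#' Cluster unique transcripts into clones
#'
#' Transcripts are partitioned by gene-level V call, gene-level J call and
#' CDR3 amino-acid length; within each partition the CDR3 nucleotide
#' sequences are greedily clustered at 90% identity.  Each clone's
#' representative is its highest-abundance member.
#'
#' @param transcripts Annotated transcript table with `v_call`, `j_call`,
#'   `cdr3_nt`, `cdr3_aa` and `abundance`.
#' @param cdr3_identity Clone identity threshold (default 0.90).
#' @return The transcripts with `clone_id` (character) and `is_representative`
#'   columns; rows lacking a CDR3 or gene call get `clone_id = NA` (their
#'   count is reported via `message()`).
#' @export
cluster_clones <- function(transcripts, cdr3_identity = 0.90) {
  x <- transcripts
  x$clone_id <- NA_character_
  x$is_representative <- FALSE
  usable <- !is.na(x$v_call) & !is.na(x$j_call) & !is.na(x$cdr3_nt) &
    nzchar(x$cdr3_nt)
  if (any(!usable)) {
    message(sum(!usable), " transcript(s) without V/J call or CDR3 excluded from clonotyping")
  }
  if (!any(usable)) return(x)
  grp_key <- paste(gene_of(x$v_call), gene_of(x$j_call),
                   nchar(x$cdr3_aa), sep = "|")
  for (g in unique(grp_key[usable])) {
    idx <- which(usable & grp_key == g)
    recs <- data.frame(read_id = as.character(idx), nt = x$cdr3_nt[idx],
                       abundance = x$abundance[idx], stringsAsFactors = FALSE)
    recs <- greedy_cluster(recs, cdr3_identity)
    x$clone_id[idx] <- paste0(gsub("\\|", "_", g), "_", recs$cluster)
  }
  # representative = highest-abundance member (ties: lexicographic sequence)
  for (cid in unique(x$clone_id[usable])) {
    m <- which(x$clone_id %in% cid)
    rep_i <- m[order(-x$abundance[m], x$nt[m])][1]
    x$is_representative[rep_i] <- TRUE
  }
  x
}

#' Build a gene-specific substitution profile (GSSP)
#'
#' For one V gene, pools clone representatives across repertoires and tabulates
#' the frequency of each amino-acid substitution at each IMGT position.  In
#' `per_observed` mode (default) the denominator at a position is the number
#' of representatives observing it (representatives without hypermutation
#' included); in `per_mutated` mode it is the number of representatives
#' mutated there, so frequencies at a position sum to 1 when any mutation was
#' observed.  Profiles built from fewer than `min_clones` representatives are
#' withheld (returns `NULL` with a message).
#'
#' @param representatives Annotated transcript rows (clone representatives)
#'   with `v_call`, list-columns `shm_aa_subs` and `numbering`.
#' @param v_gene Gene-level V name (e.g. `"IGHV-T1"`).
#' @param min_clones Minimum representatives (default 100).
#' @param mode `"per_observed"` or `"per_mutated"`.
#' @return Object of class `abrep_gssp`: list with `v_gene`, `n_clones`,
#'   `normalization_mode`, and `freq`
#'   (`data.frame(position, aa, count, coverage, freq)`), or `NULL` when
#'   withheld.
#' @export
build_gssp <- function(representatives, v_gene, min_clones = 100,
                       mode = c("per_observed", "per_mutated")) {
  mode <- match.arg(mode)
  if (!any(gene_of(representatives$v_call) == v_gene, na.rm = TRUE))
    stop("no representatives with V gene ", v_gene)
  reps <- representatives[!is.na(representatives$v_call) &
                            gene_of(representatives$v_call) == v_gene, ,
                          drop = FALSE]
  n <- nrow(reps)
  if (n < min_clones) {
    message("GSSP for ", v_gene, " withheld: ", n, " clone(s) < ", min_clones)
    return(NULL)
  }
  # coverage: representatives observing each IMGT V position (integer labels)
  cov <- new.env(parent = emptyenv())
  sub_count <- new.env(parent = emptyenv())
  mut_at <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    num <- reps$numbering[[i]]$imgt
    pos <- num$position[grepl("^[0-9]+$", num$position)]
    pos <- pos[as.integer(pos) <= 104]
    for (p in pos) assign(p, (get0(p, cov) %||% 0L) + 1L, cov)
    sh <- reps$shm_aa_subs[[i]]
    if (!is.null(sh) && nrow(sh)) {
      for (k in seq_len(nrow(sh))) {
        key <- paste0(sh$imgt_pos[k], "|", sh$observed_aa[k])
        assign(key, (get0(key, sub_count) %||% 0L) + 1L, sub_count)
        pk <- as.character(sh$imgt_pos[k])
        assign(pk, (get0(pk, mut_at) %||% 0L) + 1L, mut_at)
      }
    }
  }
  keys <- ls(sub_count)
  if (length(keys)) {
    parts <- strsplit(keys, "|", fixed = TRUE)
    freq <- data.frame(position = as.integer(vapply(parts, `[[`, "", 1)),
                       aa = vapply(parts, `[[`, "", 2),
                       count = vapply(keys, get0, 0L, envir = sub_count,
                                      USE.NAMES = FALSE),
                       stringsAsFactors = FALSE)
  } else {
    freq <- data.frame(position = integer(0), aa = character(0),
                       count = integer(0), stringsAsFactors = FALSE)
  }
  freq$coverage <- vapply(as.character(freq$position), function(p)
    get0(p, cov) %||% 0L, 0L, USE.NAMES = FALSE)
  denom <- if (mode == "per_observed") freq$coverage else
    vapply(as.character(freq$position), function(p)
      get0(p, mut_at) %||% 0L, 0L, USE.NAMES = FALSE)
  freq$freq <- ifelse(denom > 0, freq$count / denom, 0)
  freq <- freq[order(freq$position, freq$aa), , drop = FALSE]
  rownames(freq) <- NULL
  coverage <- vapply(ls(cov), get0, 0L, envir = cov, USE.NAMES = TRUE)
  coverage <- coverage[order(as.integer(names(coverage)))]
  structure(list(v_gene = v_gene, n_clones = n, normalization_mode = mode,
                 freq = freq, coverage = coverage),
            class = "abrep_gssp")
}

#' @export
print.abrep_gssp <- function(x, ...) {
  cat(sprintf("GSSP for %s: %d clones, %d substitution cells, mode=%s\n",
              x$v_gene, x$n_clones, nrow(x$freq), x$normalization_mode))
  invisible(x)
}

# frequency lookup; 0 when the cell is absent but the position is covered
gssp_freq <- function(gssp, position, aa) {
  i <- which(gssp$freq$position == position & gssp$freq$aa == aa)
  if (length(i)) gssp$freq$freq[i[1]] else 0
}

#' Pearson concordance of two substitution profiles
#'
#' Correlates the substitution frequencies of two GSSPs of the same gene over
#' the (position, amino acid) cells of positions covered in both profiles
#' (cells absent from one profile contribute frequency 0).
#'
#' @param a,b `abrep_gssp` objects with identical `v_gene` and
#'   `normalization_mode`.
#' @return Pearson r, or `NA` when no shared cells exist.
#' @export
compare_gssp <- function(a, b) {
  stopifnot(inherits(a, "abrep_gssp"), inherits(b, "abrep_gssp"))
  if (a$v_gene != b$v_gene) stop("profiles are for different V genes")
  if (a$normalization_mode != b$normalization_mode)
    stop("profiles use different normalization modes")
  shared <- intersect(names(a$coverage)[a$coverage > 0],
                      names(b$coverage)[b$coverage > 0])
  cells <- unique(rbind(a$freq[as.character(a$freq$position) %in% shared,
                               c("position", "aa")],
                        b$freq[as.character(b$freq$position) %in% shared,
                               c("position", "aa")]))
  if (nrow(cells) < 2) return(NA_real_)
  fa <- mapply(gssp_freq, cells$position, cells$aa, MoreArgs = list(gssp = a))
  fb <- mapply(gssp_freq, cells$position, cells$aa, MoreArgs = list(gssp = b))
  if (sd(fa) == 0 || sd(fb) == 0) return(NA_real_)
  cor(fa, fb)
}

#' Score the rarity of mutations in an antibody sequence
#'
#' Identifies the amino-acid substitutions of the input relative to the
#' assigned germline V and scores each against the gene's GSSP:
#' `rarity = (1 - frequency) * 100` (percent), with substitutions below the
#' `rare_threshold` frequency flagged as rare.
#'
#' @param sequence Nucleotide (default) or amino-acid transcript sequence.
#' @param v_call Germline V allele the sequence derives from.
#' @param gssp_db Named list of `abrep_gssp` objects keyed by gene-level name,
#'   or a single `abrep_gssp`.
#' @param germline `abrep_germline` reference.
#' @param is_aa Set `TRUE` when `sequence` is amino acids.
#' @param rare_threshold Frequency below which a mutation is "rare"
#'   (default 0.005, i.e. 0.5%).
#' @return `data.frame(position, germline_aa, observed_aa, frequency, rarity,
#'   is_rare)`, one row per substitution (0 rows for a germline-identical
#'   input).
#' @export
mutation_rarity <- function(sequence, v_call, gssp_db, germline,
                            is_aa = FALSE, rare_threshold = 0.005) {
  gene <- gene_of(v_call)
  gssp <- if (inherits(gssp_db, "abrep_gssp")) gssp_db else gssp_db[[gene]]
  if (is.null(gssp)) stop("no GSSP available for gene ", gene)
  germ_v <- germline_get(germline, v_call)
  if (is_aa) {
    germ_aa <- translate_nt(germ_v$ungapped_nt)
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(germ_aa),
      subject = Biostrings::AAString(sequence),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 4)
    pa <- chars(as.character(Biostrings::alignedPattern(aln)))
    sa <- chars(as.character(Biostrings::alignedSubject(aln)))
    r0 <- Biostrings::start(Biostrings::pattern(aln)) - 1L
    rpos <- ifelse(pa == "-", NA_integer_, r0 + cumsum(pa != "-"))
    keep <- !is.na(rpos) & sa != "-" & pa != sa & pa != "X" & sa != "X"
    aamap <- imgt_aa_pos(germ_v)[seq(1, nchar(germ_v$ungapped_nt), by = 3)]
    subs <- data.frame(imgt_pos = aamap[rpos[keep]],
                       germline_aa = pa[keep], observed_aa = sa[keep],
                       stringsAsFactors = FALSE)
  } else {
    v_res <- align_local(germ_v$ungapped_nt, sequence)
    subs <- compute_shm(v_res, germ_v)$shm_aa_subs
  }
  freq <- mapply(gssp_freq, subs$imgt_pos, subs$observed_aa,
                 MoreArgs = list(gssp = gssp))
  data.frame(position = subs$imgt_pos, germline_aa = subs$germline_aa,
             observed_aa = subs$observed_aa,
             frequency = as.numeric(freq),
             rarity = (1 - as.numeric(freq)) * 100,
             is_rare = as.numeric(freq) < rare_threshold,
             stringsAsFactors = FALSE)
}

#' Write / read a GSSP as TSV with a JSON sidecar
#'
#' The TSV carries one row per (gene, position, amino acid) with its count,
#' coverage and frequency; the sidecar records the normalization mode and
#' clone count.
#'
#' @param gssp An `abrep_gssp`.
#' @param path TSV output path (sidecar at `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_gssp <- function(gssp, path) {
  df <- cbind(gene = gssp$v_gene, gssp$freq, n_clones = gssp$n_clones)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(v_gene = gssp$v_gene, n_clones = gssp$n_clones,
                            normalization_mode = gssp$normalization_mode,
                            coverage = as.list(gssp$coverage)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gssp
#' @export
read_gssp <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  coverage <- unlist(meta$coverage)
  structure(list(v_gene = meta$v_gene, n_clones = meta$n_clones,
                 normalization_mode = meta$normalization_mode,
                 freq = df[, c("position", "aa", "count", "coverage", "freq")],
                 coverage = coverage[order(as.integer(names(coverage)))]),
            class = "abrep_gssp")
}
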