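# N-glycosylation sequon detection and gene-specific N-glycosylation
# profiles (GSNP).

#' Scan an amino-acid sequence for N-glycosylation sequons
#'
#' Canonical N-X-S/T rule with the proline exclusion: positions `i` with
#' `seq[i] == "N"`, `seq[i+1] != "P"` and `seq[i+2] %in% c("S", "T")`
#' (Asn-Pro-Ser/Thr motifs are not sequons).
#'
#' @param aa Amino-acid string.
#' @return Integer vector of Asn positions (1-based); empty when none.
#' @export
scan_sequons <- function(aa) {
  n <- nchar(aa)
  if (n < 3) return(integer(0))
  b <- chars(aa)
  i <- seq_len(n - 2)
  i[b[i] == "N" & b[i + 1] != "P" & b[i + 2] %in% c("S", "T")]
}

#' Build gene-specific N-glycosylation profiles
#'
#' For each V gene, transcripts with hypermutation above `min_shm_pct` are
#' eligible; for each eligible transcript, sequons present in the transcript
#' but absent at the homologous IMGT positions of its germline V are counted
#' as hypermutation-introduced.  Sequon positions are reported as the Asn's
#' IMGT position; a sequon is counted only if all three residues are
#' numbered.  Frequencies are counts divided by the number of eligible
#' transcripts of the gene.
#'
#' Note the sequon rule is sequence-based; relative to predictions filtered
#' through a structure-aware neural network, the reported frequencies are an
#' upper bound.
#'
#' @param transcripts Annotated transcript table (with `shm_nt_pct` and the
#'   `numbering` list-column).
#' @param germline `abrep_germline` reference.
#' @param min_shm_pct Eligibility threshold, percent (default 1.0; the
#'   threshold is strict: a transcript at exactly `min_shm_pct` is excluded).
#' @return Named list (by V gene) of `abrep_gsnp` objects: `v_gene`,
#'   `n_eligible`, `freq` (`data.frame(position, count, freq)`).
#' @export
build_gsnp <- function(transcripts, germline, min_shm_pct = 1.0) {
  x <- transcripts[!is.na(transcripts$v_call), , drop = FALSE]
  genes <- unique(gene_of(x$v_call))
  out <- list()
  for (g in genes) {
    rows <- which(gene_of(x$v_call) == g)
    elig <- rows[!is.na(x$shm_nt_pct[rows]) & x$shm_nt_pct[rows] > min_shm_pct]
    counts <- new.env(parent = emptyenv())
    for (i in elig) {
      num <- x$numbering[[i]]$imgt
      if (is.null(num) || nrow(num) == 0) next
      num <- num[order(num$aa_pos), , drop = FALSE]
      aa <- paste(num$residue, collapse = "")
      hits <- scan_sequons(aa)
      if (!length(hits)) next
      germ_v <- germline_get(germline, x$v_call[i])
      germ_seq <- scan_sequons(translate_nt(germ_v$ungapped_nt))
      aamap <- imgt_aa_pos(germ_v)[seq(1, nchar(germ_v$ungapped_nt), by = 3)]
      germ_labels <- as.character(aamap[germ_seq])
      for (h in hits) {
        # all three residues must be numbered (rows h, h+1, h+2 exist by
        # construction of `hits`); position label of the Asn
        lab <- num$position[h]
        if (lab %in% germ_labels) next  # germline-encoded sequon: excluded
        assign(lab, (get0(lab, counts) %||% 0L) + 1L, counts)
      }
    }
    labs <- ls(counts)
    freq <- data.frame(position = labs,
                       count = vapply(labs, get0, 0L, envir = counts,
                                      USE.NAMES = FALSE),
                       stringsAsFactors = FALSE)
    freq$freq <- if (length(elig)) freq$count / length(elig) else numeric(nrow(freq))
    freq <- freq[order(suppressWarnings(as.numeric(freq$position)),
                       freq$position), , drop = FALSE]
    rownames(freq) <- NULL
    out[[g]] <- structure(list(v_gene = g, n_eligible = length(elig),
                               freq = freq), class = "abrep_gsnp")
  }
  out
}

#' @export
print.abrep_gsnp <- function(x, ...) {
  cat(sprintf("GSNP for %s: %d eligible transcripts, %d positions with introduced sequons\n",
              x$v_gene, x$n_eligible, nrow(x$freq)))
  invisible(x)
}

#' Write GSNPs as TSV
#' @param gsnps Named list of `abrep_gsnp` (as returned by [build_gsnp()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gsnp <- function(gsnps, path) {
  rows <- lapply(gsnps, function(g)
    if (nrow(g$freq)) cbind(gene = g$v_gene, g$freq, n_eligible = g$n_eligible)
    else NULL)
  rows <- Filter(Negate(is.null), rows)
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), position = character(0),
               count = integer(0), freq = numeric(0), n_eligible = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
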