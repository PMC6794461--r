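#' Read a FASTQ file into a record table
#'
#' Phred+33 encoding is assumed (Illumina).  The sequence/quality length
#' agreement of every record is validated.
#'
#' @param path FASTQ file path.
#' @return A `data.frame` with columns `read_id`, `nt`, `qual` (Phred+33
#'   string), `umi` (`NA`), `abundance` (1).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  # structural validation first (four-line records): the C parser does not
  # verify sequence/quality agreement or truncation
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ (", path, "): record ",
         length(lines) %/% 4 + 1, " is incomplete")
  }
  i1 <- seq(1, length(lines), by = 4)
  if (any(substr(lines[i1], 1, 1) != "@") ||
      any(substr(lines[i1 + 2], 1, 1) != "+")) {
    bad <- which(substr(lines[i1], 1, 1) != "@" |
                   substr(lines[i1 + 2], 1, 1) != "+")[1]
    stop("malformed FASTQ (", path, "): record ", bad,
         " does not follow the @/+ layout")
  }
  bad <- which(nchar(lines[i1 + 1]) != nchar(lines[i1 + 3]))
  if (length(bad)) {
    stop("FASTQ record ", bad[1], " (", lines[i1[bad[1]]],
         "): sequence and quality lengths differ")
  }
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(set)$qualities)
  new_records(read_id = sub("[ \t].*$", "", names(set)),
              nt = as.character(set), qual = quals)
}

#' Read a FASTA file into a record table
#'
#' @param path FASTA file path.
#' @return A record `data.frame` as in [read_fastq()], with `qual = NA`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  new_records(read_id = sub("[ \t].*$", "", names(set)),
              nt = as.character(set))
}

#' Construct a sequence-record table
#'
#' The tabular representation of sequencing reads used throughout the package:
#' one row per read with optional Phred+33 qualities, optional UMI, and an
#' abundance (number of exact copies collapsed into the row, >= 1).
#'
#' @param read_id,nt Character vectors.
#' @param qual Phred+33 strings or `NA`.
#' @param umi UMI strings or `NA`.
#' @param abundance Positive integers (default 1).
#' @return A `data.frame` with those five columns.
#' @export
new_records <- function(read_id, nt, qual = NA_character_, umi = NA_character_,
                        abundance = 1L) {
  nt <- toupper(nt)
  n <- length(read_id)
  df <- data.frame(read_id = as.character(read_id), nt = rep_len(nt, n),
                   qual = rep_len(as.character(qual), n),
                   umi = rep_len(as.character(umi), n),
                   abundance = rep_len(as.integer(abundance), n),
                   stringsAsFactors = FALSE)
  qlen <- nchar(df$qual)
  bad <- !is.na(df$qual) & qlen != nchar(df$nt)
  if (any(bad)) stop("record ", df$read_id[which(bad)[1]],
                     ": quality length does not match sequence length")
  if (any(df$abundance < 1L)) stop("abundance must be >= 1")
  df
}

#' Write records to FASTQ
#' @param records A record table; all rows must carry qualities.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  if (any(is.na(records$qual))) stop("records without qualities; write FASTA instead")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", records$read_id, "\n", records$nt, "\n+\n", records$qual), con)
  invisible(path)
}

# ---- annotated-FASTA dialect -------------------------------------------------
# Curated transcripts are stored as FASTA with key=value annotation pairs in
# the header: ">id key=value;key=value;...".  ";" and "=" are reserved and may
# not occur inside values.

ANNOT_FIELDS <- c("v_call", "d_call", "j_call", "isotype", "cdr3_nt", "cdr3_aa",
                  "shm_nt_pct", "productive", "abundance", "umi",
                  "repertoire_id", "donor_id")
ANNOT_NUM <- c("shm_nt_pct", "abundance")
ANNOT_LOGI <- "productive"

annot_header <- function(row) {
  parts <- character(0)
  for (f in ANNOT_FIELDS) {
    v <- row[[f]]
    if (is.null(v) || length(v) == 0 || is.na(v)) next
    v <- if (f %in% ANNOT_NUM) num_to_chr(as.numeric(v)) else as.character(v)
    if (grepl("[;=]", v)) {
      stop("reserved delimiter ';' or '=' inside value of field '", f, "': ", v)
    }
    parts <- c(parts, paste0(f, "=", v))
  }
  paste0(row$read_id, " ", paste(parts, collapse = ";"))
}

#' Write annotated transcripts to the annotated-FASTA dialect
#'
#' Headers carry semicolon-delimited `key=value` annotation (gene calls,
#' isotype, CDR3, hypermutation level, abundance, donor/repertoire ids) after
#' the sequence identifier; fields that are absent are omitted.
#' `parse_annotated_header()` inverts the encoding exactly.
#'
#' @param transcripts An annotated transcript table (see
#'   [annotate_repertoire()]); minimally `read_id` and `nt` plus any of the
#'   annotation columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_fasta <- function(transcripts, path) {
  headers <- vapply(seq_len(nrow(transcripts)), function(i)
    annot_header(as.list(transcripts[i, , drop = FALSE])), character(1))
  writeLines(paste0(">", headers, "\n", transcripts$nt), path)
  invisible(path)
}

#' Parse one annotated-FASTA header line
#'
#' @param header Header text (with or without the leading `">"`).
#' @return Named list with `read_id` and every encoded annotation field;
#'   fields absent from the header are `NA`.
#' @export
parse_annotated_header <- function(header) {
  header <- sub("^>", "", header)
  id <- sub("[ \t].*$", "", header)
  rest <- sub("^[^ \t]+[ \t]*", "", header)
  out <- list(read_id = id)
  for (f in ANNOT_FIELDS) out[[f]] <- NA
  out$abundance <- NA_integer_
  if (nzchar(rest)) {
    for (kv in strsplit(rest, ";", fixed = TRUE)[[1]]) {
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 1) stop("malformed annotation token (no '='): ", kv)
      k <- substr(kv, 1, eq - 1)
      v <- substr(kv, eq + 1, nchar(kv))
      if (k %in% ANNOT_NUM) v <- as.numeric(v)
      if (k %in% ANNOT_LOGI) v <- as.logical(v)
      out[[k]] <- v
    }
  }
  out$abundance <- as.integer(out$abundance %||% NA_integer_)
  out
}

#' Read an annotated-FASTA file back into a transcript table
#' @param path File written by [write_annotated_fasta()].
#' @return A `data.frame` with one row per record.
#' @export
read_annotated_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  rows <- lapply(names(set), parse_annotated_header)
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  df$nt <- as.character(set)
  df$productive <- as.logical(df$productive)
  df
}
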