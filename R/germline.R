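#' Load an IMGT-gapped germline reference FASTA
#'
#' Reads a germline segment reference (V/D/J/constant-domain entries).  V
#' entries may carry IMGT gap characters (`"."`, with `"-"` accepted and
#' normalised on load) marking deleted positions of the standardised
#' variable-domain alignment; the gapped column index of each retained base is
#' recorded so that transcript positions can later be reported in IMGT
#' coordinates.
#'
#' Headers must start with the allele name (`GENE*NN`); either a bare name or
#' the IMGT pipe-delimited dialect (allele name in the second field) is
#' accepted.  Segment kind and chain are inferred from the standard locus
#' prefix (`IGHV...` = heavy V, `IGKJ...` = kappa J, `IGHM/IGHG/...` =
#' constant).
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` of class `abrep_germline`, one row per entry, with
#'   columns `allele_name`, `gene`, `segment_kind` (V/D/J/C), `chain`
#'   (heavy/kappa/lambda), `gapped_nt`, `ungapped_nt`, list-column
#'   `imgt_nt_pos` (gapped column index of each ungapped base) and, for V
#'   segments whose gapped span covers the conserved 2nd-Cys codon (IMGT
#'   position 104), `cys104_start` (1-based ungapped index of that codon).
#' @export
load_germline_fasta <- function(path) {
  if (!file.exists(path)) stop("germline FASTA not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("empty germline FASTA: ", path)
    return(empty_germline())
  }
  headers <- names(set)
  allele <- vapply(headers, function(h) {
    h1 <- strsplit(h, "[ \t]")[[1]][1]
    if (grepl("|", h1, fixed = TRUE)) {
      f <- strsplit(h1, "|", fixed = TRUE)[[1]]
      if (length(f) >= 2 && grepl("\\*", f[2])) f[2] else f[1]
    } else h1
  }, character(1), USE.NAMES = FALSE)
  bad <- !grepl("^[A-Za-z0-9._/-]+\\*[0-9]+$", allele)
  if (any(bad)) {
    stop("germline header does not contain an allele name (GENE*NN): ",
         headers[which(bad)[1]])
  }
  if (anyDuplicated(allele)) {
    stop("duplicate germline allele name: ",
         allele[duplicated(allele)][1])
  }
  gapped <- toupper(as.character(set))
  gapped <- gsub("-", ".", gapped, fixed = TRUE)
  if (any(grepl("[^ACGTN.]", gapped))) {
    stop("germline sequence contains characters outside A/C/G/T/N/./-: ",
         allele[grep("[^ACGTN.]", gapped)[1]])
  }
  ungapped <- gsub(".", "", gapped, fixed = TRUE)
  imgt_nt_pos <- lapply(gapped, function(g) which(chars(g) != "."))
  kind <- infer_segment_kind(allele)
  chain <- infer_chain(allele)
  cys <- mapply(function(k, pos) {
    if (k != "V") return(NA_integer_)
    i <- match(310L, pos)  # IMGT nt position 310 = first base of codon 104
    if (is.na(i) || length(pos) < i + 2 || pos[i + 1] != 311L || pos[i + 2] != 312L)
      return(NA_integer_)
    i
  }, kind, imgt_nt_pos)
  db <- data.frame(
    allele_name = allele, gene = gene_of(allele), segment_kind = kind,
    chain = chain, gapped_nt = gapped, ungapped_nt = ungapped,
    cys104_start = as.integer(cys), stringsAsFactors = FALSE
  )
  db$imgt_nt_pos <- imgt_nt_pos
  rownames(db) <- NULL
  class(db) <- c("abrep_germline", "data.frame")
  db
}

empty_germline <- function() {
  db <- data.frame(allele_name = character(0), gene = character(0),
                   segment_kind = character(0), chain = character(0),
                   gapped_nt = character(0), ungapped_nt = character(0),
                   cys104_start = integer(0), stringsAsFactors = FALSE)
  db$imgt_nt_pos <- list()
  class(db) <- c("abrep_germline", "data.frame")
  db
}

infer_segment_kind <- function(allele) {
  k <- substr(allele, 4, 4)
  ifelse(k %in% c("V", "D", "J"), k, "C")
}

infer_chain <- function(allele) {
  ch <- substr(allele, 3, 3)
  c(H = "heavy", K = "kappa", L = "lambda")[ch]
}

#' Build a germline reference from in-memory sequences
#'
#' Convenience constructor used by the simulator and tests: writes the given
#' named sequences to a temporary FASTA and loads them through
#' [load_germline_fasta()] so both paths share validation.
#'
#' @param seqs Named character vector (names = allele names, values = possibly
#'   gapped nucleotide sequences).
#' @return An `abrep_germline` data.frame.
#' @export
germline_from_sequences <- function(seqs) {
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), tf)
  load_germline_fasta(tf)
}

#' Write a germline reference to FASTA
#' @param db An `abrep_germline` data.frame.
#' @param path Output file path.
#' @param gapped Write the IMGT-gapped (`TRUE`, default) or ungapped sequence.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(db, path, gapped = TRUE) {
  seqs <- if (gapped) db$gapped_nt else db$ungapped_nt
  writeLines(paste0(">", db$allele_name, "\n", seqs), path)
  invisible(path)
}

germline_get <- function(db, allele) {
  i <- match(allele, db$allele_name)
  if (is.na(i)) stop("allele not in germline reference: ", allele)
  db[i, , drop = FALSE]
}

germline_subset <- function(db, kind = NULL, chain = NULL) {
  keep <- rep(TRUE, nrow(db))
  if (!is.null(kind)) keep <- keep & db$segment_kind %in% kind
  if (!is.null(chain)) keep <- keep & db$chain %in% chain
  db[keep, , drop = FALSE]
}

# IMGT amino-acid position of each ungapped nt of a V gene: ceiling(gapped/3)
imgt_aa_pos <- function(germ_row) {
  ceiling(germ_row$imgt_nt_pos[[1]] / 3)
}

#' Validate a germline reference file
#'
#' Loads the file and reports per-segment counts plus basic sanity checks
#' (2nd-Cys codon located for gapped V entries).  Used by the
#' `abrep germline-validate` command.
#'
#' @param path FASTA path.
#' @return Invisibly, the loaded reference; prints a summary.
#' @export
validate_germline <- function(path) {
  db <- load_germline_fasta(path)
  counts <- table(factor(db$segment_kind, levels = c("V", "D", "J", "C")))
  cat(sprintf("germline reference: %d entries (V=%d D=%d J=%d C=%d)\n",
              nrow(db), counts["V"], counts["D"], counts["J"], counts["C"]))
  v <- db[db$segment_kind == "V", ]
  if (nrow(v)) {
    nocys <- v$allele_name[is.na(v$cys104_start)]
    if (length(nocys)) {
      cat("V entries without a locatable 2nd-Cys (IMGT 104) codon:",
          paste(nocys, collapse = ", "), "\n")
    } else {
      cys_aa <- vapply(seq_len(nrow(v)), function(i) {
        substr(translate_nt(substr(v$ungapped_nt[i], v$cys104_start[i],
                                   v$cys104_start[i] + 2)), 1, 1)
      }, character(1))
      if (any(cys_aa != "C"))
        cat("warning: non-Cys residue at IMGT 104 in:",
            paste(v$allele_name[cys_aa != "C"], collapse = ", "), "\n")
      else cat("all V entries carry Cys at IMGT position 104\n")
    }
  }
  invisible(db)
}
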