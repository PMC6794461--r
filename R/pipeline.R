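# End-to-end orchestration: (simulate | read) -> QC -> annotate -> curate ->
# clonotype -> profiles, from a single config, with a machine-readable run
# manifest for provenance.

#' Build or load a pipeline configuration
#'
#' A config is a plain named list (or YAML file with the same structure):
#' `germline` (path, or `NULL` to use the toy reference), `input` (FASTQ/FASTA
#' path, or `NULL` to simulate), `simulate` (list of [sim_config()]
#' arguments), `chain`, `curation_mode` (`"umi"` or `"cluster"`), `qc` (list
#' of [qc_thresholds()] arguments), `curation` (list of [curation_params()]
#' arguments), `clone_identity`, `gssp_min_clones`, `gsnp_min_shm`, `seed`,
#' `out_dir`.
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(germline = NULL, input = NULL, simulate = list(),
                   chain = "heavy", curation_mode = "cluster",
                   qc = list(), curation = list(),
                   clone_identity = 0.90, gssp_min_clones = 100,
                   gssp_mode = "per_observed", gsnp_min_shm = 1.0,
                   seed = 1, out_dir = "abrep_out",
                   repertoire_id = "rep1", donor_id = "donor1")
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$curation_mode %in% c("umi", "cluster"))
    stop("curation_mode must be 'umi' or 'cluster'")
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    stop("input file does not exist: ", cfg$input)
  if (is.character(cfg$germline) && !file.exists(cfg$germline))
    stop("germline file does not exist: ", cfg$germline)
  cfg
}

#' Run the full pipeline
#'
#' Stages run in fixed order: acquire reads (simulation or input file), QC
#' filter, annotate, curate (UMI consensus or cluster dedup), repertoire
#' filter, clonotype clustering, GSSP and GSNP construction.  Every stage's
#' record counts and parameters are written to `manifest.json` in the output
#' directory along with per-stage artifacts; a rerun with identical config
#' and inputs is byte-identical.
#'
#' @param config See [pipeline_config()].
#' @return Invisibly, a list with the manifest and the main in-memory
#'   results (`annotated`, `unique`, `clones`, `gssps`, `gsnps`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "abrep",
                   version = as.character(utils::packageVersion("abrep")),
                   config = cfg[setdiff(names(cfg), "germline_db")],
                   stages = list())
  stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message("[abrep] ", name, ": ",
            paste(names(list(...)), unlist(list(...)), sep = "=", collapse = " "))
  }

  # germline
  if (is.character(cfg$germline)) {
    germ <- load_germline_fasta(cfg$germline)
    germ_hash <- unname(tools::md5sum(cfg$germline))
  } else {
    germ <- make_toy_germline(cfg$seed)
    gf <- file.path(cfg$out_dir, "germline_toy.fasta")
    write_germline_fasta(germ, gf)
    germ_hash <- unname(tools::md5sum(gf))
  }
  stage("germline", n_entries = nrow(germ), md5 = germ_hash)

  # reads
  truth <- NULL
  if (!is.null(cfg$input)) {
    records <- if (grepl("\\.(fq|fastq)$", cfg$input)) read_fastq(cfg$input)
               else read_fasta(cfg$input)
  } else {
    sim_args <- utils::modifyList(list(seed = cfg$seed, germline = germ,
                                       chain = cfg$chain,
                                       repertoire_id = cfg$repertoire_id,
                                       donor_id = cfg$donor_id),
                                  cfg$simulate)
    sim <- simulate_repertoire(do.call(sim_config, sim_args))
    records <- sim$records
    truth <- sim$truth
  }
  stage("reads", n_reads = nrow(records))

  # QC
  qc <- do.call(qc_thresholds, cfg$qc)
  qcres <- qc_filter(records, qc)
  stage("qc_filter", kept = nrow(qcres$kept), rejected = nrow(qcres$rejected))

  # curation (on QC-passed reads)
  params <- do.call(curation_params, cfg$curation)
  cur <- if (cfg$curation_mode == "umi") umi_consensus(qcres$kept, params)
         else cluster_dedup_no_umi(qcres$kept, params)
  stage("curate", mode = cfg$curation_mode, unique = nrow(cur$unique),
        dropped = nrow(cur$dropped))
  rf <- repertoire_filter(cur$unique, params)
  stage("repertoire_filter", keep = rf$keep, n_unique = rf$n_unique)

  # annotation of unique transcripts
  ann <- annotate_repertoire(cur$unique, germ, chain = cfg$chain,
                             repertoire_id = cfg$repertoire_id,
                             donor_id = cfg$donor_id)
  write_annotated_fasta(ann, file.path(cfg$out_dir, "unique_annotated.fasta"))
  stage("annotate", n_transcripts = nrow(ann),
        n_assigned = sum(!is.na(ann$v_call)),
        n_productive = sum(ann$productive))

  # clonotypes
  clones <- cluster_clones(ann, cdr3_identity = cfg$clone_identity)
  n_clones <- length(unique(clones$clone_id[!is.na(clones$clone_id)]))
  utils::write.table(
    clones[, c("read_id", "v_call", "j_call", "cdr3_aa", "clone_id",
               "is_representative")],
    file.path(cfg$out_dir, "clones.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  stage("clonotype", n_clones = n_clones)

  # profiles from clone representatives
  reps <- clones[clones$is_representative, , drop = FALSE]
  gssps <- list()
  for (g in unique(gene_of(reps$v_call[!is.na(reps$v_call)]))) {
    p <- build_gssp(reps, g, min_clones = cfg$gssp_min_clones,
                    mode = cfg$gssp_mode)
    if (!is.null(p)) {
      gssps[[g]] <- p
      write_gssp(p, file.path(cfg$out_dir, paste0("gssp_", g, ".tsv")))
    }
  }
  stage("gssp", n_profiles = length(gssps))
  gsnps <- build_gsnp(ann, germ, min_shm_pct = cfg$gsnp_min_shm)
  write_gsnp(gsnps, file.path(cfg$out_dir, "gsnp.tsv"))
  stage("gsnp", n_genes = length(gsnps))

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(manifest = manifest, annotated = ann, unique = cur$unique,
                 clones = clones, gssps = gssps, gsnps = gsnps,
                 truth = truth))
}
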