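# Synthetic repertoire generation with full ground truth.  The generator
# emulates the error processes the curation stages are designed to remove:
# V(D)J recombination from a small germline set, hotspot-biased point
# hypermutation, multiple mRNA copies per cell, PCR duplication with per-base
# error, Phred quality strings with consistent miscall injection, and optional
# UMIs with collisions.

# most-used human codon per amino acid, plus one alternative for jitter
.CODON1 <- c(A="GCC", C="TGT", D="GAC", E="GAG", F="TTC", G="GGC", H="CAC",
             I="ATC", K="AAG", L="CTG", M="ATG", N="AAC", P="CCC", Q="CAG",
             R="AGA", S="AGC", T="ACC", V="GTG", W="TGG", Y="TAC")
.CODON2 <- c(A="GCT", C="TGC", D="GAT", E="GAA", F="TTT", G="GGA", H="CAT",
             I="ATT", K="AAA", L="CTC", M="ATG", N="AAT", P="CCT", Q="CAA",
             R="CGT", S="TCC", T="ACA", V="GTC", W="TGG", Y="TAT")

.VH_BASE <- "EVQLVESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVSAISGSGGSTYYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYC"
.VH_GAPS <- c(31:33, 60:64)            # IMGT aa positions deleted in the toy VH
.VK_BASE <- "DIQMTQSPSSLSASVGDRVTITCRASQSISSYLNWYQQKPGKAPKLLIYAASSLQSGVPSRFSGSGSGTDFTLTISSLQPEDFATYYC"
.VK_GAPS <- c(27:32, 58:63, 81:84)

.TOY_J <- c(
  "IGHJ-T1*01" = "TTTGACTACTGGGGCCAAGGAACCCTGGTCACCGTCTCCTCA",          # FDY|WGQG...
  "IGHJ-T2*01" = "TACTACTACTACGGTATGGACGTCTGGGGCCAAGGGACCACGGTCACC",    # YYYYGMDV|WGQG...
  "IGKJ-T1*01" = "TGGACGTTCGGCCAAGGGACCAAGGTGGAGATCAAA",                # WT|FGQG...
  "IGKJ-T2*01" = "ATCACCTTCGGCCAAGGGACACGACTGGAGATTAAA"                 # IT|FGQG...
)
# nt preceding the conserved W (heavy, WGXG) / F (light, FGXG) anchor codon
.TOY_J_PREW <- c("IGHJ-T1*01" = 9L, "IGHJ-T2*01" = 24L,
                 "IGKJ-T1*01" = 6L, "IGKJ-T2*01" = 6L)

.TOY_D <- c("IGHD-T1*01" = "GGTATAGCAGCAGCTGGTAC",
            "IGHD-T2*01" = "GATTACGATTTTTGGAGTGGTTAT")

.TOY_CH1 <- c(
  "IGHM-TOY*01" = "GGGAGTGCATCCGCCCCAACCCTTTTCCCCCTCGTCTCCTGTGAGAATTCCCCG",
  "IGHG-TOY*01" = "GCCTCCACCAAGGGCCCATCGGTCTTCCCCCTGGCACCCTCCTCCAAGAGCACC",
  "IGHA-TOY*01" = "GCATCCCCGACCAGCCCCAAGGTCTTCCCGCTGAGCCTCTGCAGCACCCAGCCA"
)

aa_to_nt <- function(aa, jitter = 0.3) {
  a <- chars(aa)
  alt <- runif(length(a)) < jitter
  codons <- ifelse(alt, .CODON2[a], .CODON1[a])
  paste(codons, collapse = "")
}

# gapped V sequence (312 columns = IMGT aa positions 1..104)
gapped_v <- function(nt, gap_positions) {
  codons <- character(104)
  codons[gap_positions] <- "..."
  idx <- setdiff(1:104, gap_positions)
  starts <- seq(1, by = 3, length.out = length(idx))
  codons[idx] <- substring(nt, starts, starts + 2)
  paste(codons, collapse = "")
}

#' Generate a deterministic toy germline reference
#'
#' Builds a small IMGT-gapped reference suitable for exercising every stage of
#' the pipeline: 5 heavy-chain V alleles (4 genes), 2 kappa V, 2 D, 2 heavy
#' and 2 kappa J, and 3 heavy CH1 entries.  Every V ends with the conserved
#' 2nd-Cys codon at IMGT position 104 and every J contains a WGXG (heavy) or
#' FGXG (light) motif, so CDR3 extraction is well-posed by construction.
#'
#' @param seed Integer seed; the same seed always yields byte-identical
#'   sequences, different seeds differ in the gene-specific variable codons.
#' @return An `abrep_germline` data.frame.
#' @export
make_toy_germline <- function(seed = 1) {
  with_seed(seed, {
    seqs <- character(0)
    mk_v <- function(base_aa, gaps, n_genes, prefix) {
      out <- character(0)
      for (g in seq_len(n_genes)) {
        aa <- chars(base_aa)
        # diversify ~8 interior codons per gene; keep the terminal Cys anchor
        mut_at <- sample(seq_len(length(aa) - 1), 8)
        aa[mut_at] <- vapply(aa[mut_at], function(old)
          sample(setdiff(AA20, c(old, "C", "W")), 1), character(1))
        nt <- aa_to_nt(paste(aa, collapse = ""))
        out[sprintf("%s%d*01", prefix, g)] <- gapped_v(nt, gaps)
        if (g == 1) {  # a second allele of gene 1, two silent-ish nt apart
          nt2 <- chars(nt)
          pos <- sample(seq_len(length(nt2) - 3), 2)
          nt2[pos] <- vapply(nt2[pos], function(b)
            sample(setdiff(DNA_BASES4, b), 1), character(1))
          out[sprintf("%s%d*02", prefix, g)] <- gapped_v(paste(nt2, collapse = ""), gaps)
        }
      }
      out
    }
    seqs <- c(seqs, mk_v(.VH_BASE, .VH_GAPS, 4, "IGHV-T"))
    seqs <- c(seqs, mk_v(.VK_BASE, .VK_GAPS, 2, "IGKV-T"))
    seqs <- c(seqs, .TOY_D, .TOY_J, .TOY_CH1)
    germline_from_sequences(seqs)
  })
}

#' Simulation configuration
#'
#' Defaults describe a small but realistic bulk Rep-seq library: 2% V-region
#' hypermutation with a 3x WRC/GYW hotspot bias, about two mRNA molecules per
#' cell, three PCR copies per molecule with a 1e-4 per-base error rate, and
#' Illumina-like qualities around Q38.
#'
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @param n_cells Number of B cells to simulate.
#' @param germline `abrep_germline` reference (default: toy reference from the
#'   same seed).
#' @param chain `"heavy"` or `"kappa"`.
#' @param shm_rate Per-base substitution probability in the V(D)J region.
#' @param hotspot_multiplier Rate multiplier at WRC/GYW hotspot bases.
#' @param mrna_mean,mrna_min mRNA molecules per cell: `min + Poisson(mean - min)`.
#' @param pcr_duplicates_mean,pcr_duplicates_min PCR copies per molecule,
#'   same parameterisation.
#' @param pcr_error_rate Per-base substitution probability per PCR copy.
#' @param phred_mean,phred_sd Per-base quality model (clipped normal, 2..41);
#'   miscalls are injected with probability `10^(-Q/10)` so emitted qualities
#'   are consistent with realized errors.
#' @param miscalls Set `FALSE` to emit quality strings without injecting any
#'   miscalls (noise-free reads for exact-recovery checks).
#' @param umi_length UMI length in nt; 0 disables UMIs.
#' @param umi_collision_rate Probability a molecule reuses a UMI already
#'   assigned to a different cell.
#' @param n_region_mean Mean geometric length of each untemplated N region.
#' @param with_ch1 Append a constant-domain (CH1) tail to heavy chains.
#' @param repertoire_id,donor_id Metadata labels.
#' @return A validated list of class `abrep_sim_config`.
#' @export
sim_config <- function(seed = 1, n_cells = 100, germline = NULL,
                       chain = c("heavy", "kappa"),
                       shm_rate = 0.02, hotspot_multiplier = 3,
                       mrna_mean = 2, mrna_min = 1,
                       pcr_duplicates_mean = 3, pcr_duplicates_min = 1,
                       pcr_error_rate = 1e-4,
                       phred_mean = 38, phred_sd = 3, miscalls = TRUE,
                       umi_length = 12, umi_collision_rate = 0,
                       n_region_mean = 4, with_ch1 = TRUE,
                       repertoire_id = "sim1", donor_id = "donor1") {
  chain <- match.arg(chain)
  cfg <- list(seed = as.integer(seed), n_cells = as.integer(n_cells),
              germline = germline, chain = chain, shm_rate = shm_rate,
              hotspot_multiplier = hotspot_multiplier,
              mrna_mean = mrna_mean, mrna_min = as.integer(mrna_min),
              pcr_duplicates_mean = pcr_duplicates_mean,
              pcr_duplicates_min = as.integer(pcr_duplicates_min),
              pcr_error_rate = pcr_error_rate, phred_mean = phred_mean,
              phred_sd = phred_sd, miscalls = isTRUE(miscalls),
              umi_length = as.integer(umi_length),
              umi_collision_rate = umi_collision_rate,
              n_region_mean = n_region_mean, with_ch1 = isTRUE(with_ch1),
              repertoire_id = repertoire_id, donor_id = donor_id)
  for (f in c("shm_rate", "pcr_error_rate", "umi_collision_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0,1]")
  if (cfg$n_cells < 1) stop("n_cells must be >= 1")
  if (cfg$mrna_mean < cfg$mrna_min || cfg$pcr_duplicates_mean < cfg$pcr_duplicates_min)
    stop("distribution mean must be >= min")
  class(cfg) <- "abrep_sim_config"
  cfg
}

# per-base mutation-rate vector with WRC/GYW hotspot weighting
shm_rate_vector <- function(nt, base_rate, multiplier) {
  n <- nchar(nt)
  rate <- rep(base_rate, n)
  if (multiplier != 1 && n >= 3) {
    b <- chars(nt)
    # WRC: mutable C preceded by [AT][AG]; GYW: mutable G followed by [CT][AT]
    i <- 3:n
    wrc <- i[b[i] == "C" & b[i - 2] %in% c("A", "T") & b[i - 1] %in% c("A", "G")]
    i <- 1:(n - 2)
    gyw <- i[b[i] == "G" & b[i + 1] %in% c("C", "T") & b[i + 2] %in% c("A", "T")]
    rate[c(wrc, gyw)] <- rate[c(wrc, gyw)] * multiplier
  }
  pmin(rate, 0.95)
}

mutate_bases <- function(nt, idx) {
  if (length(idx) == 0) return(nt)
  b <- chars(nt)
  b[idx] <- vapply(b[idx], function(x) sample(setdiff(DNA_BASES4, x), 1), character(1))
  paste(b, collapse = "")
}

random_nt <- function(n) {
  if (n == 0) return("")
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

rgeom_len <- function(mean) {
  if (mean <= 0) return(0L)
  stats::rgeom(1, 1 / (mean + 1))
}

# first position at which the chain's anchor motif matches in `aa`;
# heavy: WG.G, light: FG.G
first_anchor <- function(aa, chain) {
  pat <- if (chain == "heavy") "WG.G" else "FG.G"
  m <- regexpr(pat, aa)
  if (m < 0) NA_integer_ else as.integer(m)
}

#' Simulate a repertoire with ground truth
#'
#' Runs the full generative model (see [sim_config()]) and returns both the
#' emitted reads (shuffled, as a sequencing run would deliver them) and a
#' ground-truth object recording every mapping: read -> molecule -> cell,
#' per-cell true transcript/genes/CDR3/mutations, and the realized per-gene
#' amino-acid substitution table.
#'
#' @param config An `abrep_sim_config`.
#' @return List with elements `records` (read table, one row per read),
#'   `truth` (list of data.frames `cells`, `molecules`, `reads`, `v_subs`)
#'   and `config`.
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "abrep_sim_config"))
  germ <- config$germline
  if (is.null(germ)) germ <- make_toy_germline(config$seed)
  if (nrow(germ) == 0) stop("empty germline set")
  vs <- germline_subset(germ, "V", config$chain)
  js <- germline_subset(germ, "J", config$chain)
  ds <- germline_subset(germ, "D", "heavy")
  cs <- germline_subset(germ, "C", "heavy")
  if (nrow(vs) == 0 || nrow(js) == 0)
    stop("germline set lacks V or J segments for chain ", config$chain)
  heavy <- config$chain == "heavy"

  with_seed(config$seed, {
    cells <- vector("list", config$n_cells)
    vsubs <- vector("list", config$n_cells)
    mols <- list(); reads <- list()
    umi_pool <- character(0); umi_cell <- integer(0)
    mol_n <- 0L

    for (ci in seq_len(config$n_cells)) {
      vi <- sample(nrow(vs), 1); ji <- sample(nrow(js), 1)
      v <- vs[vi, ]; j <- js[ji, ]
      j_nt_full <- j$ungapped_nt
      prew_full <- .TOY_J_PREW[[j$allele_name]] %||% 6L
      d_call <- NA_character_; d_seq <- ""
      if (heavy && nrow(ds)) {
        di <- sample(nrow(ds), 1)
        d_call <- ds$allele_name[di]
        dfull <- ds$ungapped_nt[di]
        d5 <- sample(0:2, 1); d3 <- sample(0:2, 1)
        d_seq <- substr(dfull, d5 + 1, nchar(dfull) - d3)
      }
      # junction assembly; resample until the CDR3 is stop-free and its first
      # anchor-motif hit is the true J anchor (keeps extraction well-posed)
      anchor_aa <- if (heavy) "W" else "F"
      for (try in 1:100) {
        j_trim <- sample(0:min(3, prew_full), 1)
        prew <- prew_full - j_trim
        n1 <- rgeom_len(config$n_region_mean)
        n2 <- if (heavy) rgeom_len(config$n_region_mean) else 0L
        tot <- n1 + nchar(d_seq) + n2 + prew
        fix <- (3 - tot %% 3) %% 3
        n2 <- n2 + fix  # pad to keep the J anchor in the V reading frame
        junction <- paste0(random_nt(n1), d_seq, random_nt(n2))
        j_used <- substr(j_nt_full, j_trim + 1, nchar(j_nt_full))
        cdr3_nt <- paste0(junction, substr(j_used, 1, prew))
        post_aa <- translate_nt(substr(j_used, prew + 1, prew + 12))
        cdr3_aa <- translate_nt(cdr3_nt)
        ext <- paste0(cdr3_aa, post_aa)
        fa <- first_anchor(ext, config$chain)
        ok <- !grepl("*", cdr3_aa, fixed = TRUE) &&
          !is.na(fa) && fa == nchar(cdr3_aa) + 1 && nchar(cdr3_aa) >= 3
        if (ok) break
      }
      if (!ok) stop("failed to assemble a well-posed junction for cell ", ci)
      ch1_call <- NA_character_; ch1 <- ""
      if (heavy && config$with_ch1 && nrow(cs)) {
        cc <- sample(nrow(cs), 1)
        ch1_call <- cs$allele_name[cc]; ch1 <- cs$ungapped_nt[cc]
      }
      vdj <- paste0(v$ungapped_nt, junction, j_used)
      # somatic hypermutation over the V(D)J region only
      rate <- shm_rate_vector(vdj, config$shm_rate, config$hotspot_multiplier)
      hit <- which(runif(nchar(vdj)) < rate)
      vdj_mut <- mutate_bases(vdj, hit)
      transcript <- paste0(vdj_mut, ch1)
      vlen <- nchar(v$ungapped_nt)
      n_v_mut <- sum(hit <= vlen)
      # realized amino-acid substitutions in V
      germ_aa <- translate_nt(v$ungapped_nt)
      obs_aa <- translate_nt(substr(vdj_mut, 1, vlen))
      ga <- chars(germ_aa); oa <- chars(obs_aa)
      diffpos <- which(ga != oa)
      if (length(diffpos)) {
        aamap <- imgt_aa_pos(v)
        codon_imgt <- aamap[seq(1, vlen, by = 3)][diffpos]
        vsubs[[ci]] <- data.frame(cell_id = ci, v_call = v$allele_name,
                                  imgt_pos = codon_imgt, germline_aa = ga[diffpos],
                                  observed_aa = oa[diffpos], stringsAsFactors = FALSE)
      }
      # true CDR3 after mutation; productivity from anchors + stop codons
      cdr3_mut_nt <- substr(vdj_mut, vlen + 1, vlen + nchar(cdr3_nt))
      cdr3_mut_aa <- translate_nt(cdr3_mut_nt)
      post_mut <- translate_nt(substr(vdj_mut, vlen + nchar(cdr3_nt) + 1,
                                      vlen + nchar(cdr3_nt) + 12))
      fa <- first_anchor(paste0(cdr3_mut_aa, post_mut), config$chain)
      cys_ok <- substr(translate_nt(substr(vdj_mut, vlen - 2, vlen)), 1, 1) == "C"
      anchors_ok <- cys_ok && !is.na(fa) && fa == nchar(cdr3_mut_aa) + 1
      productive <- anchors_ok && !grepl("*", translate_nt(vdj_mut), fixed = TRUE)
      cells[[ci]] <- data.frame(
        cell_id = ci, v_call = v$allele_name, d_call = d_call,
        j_call = j$allele_name, c_call = ch1_call, nt = transcript,
        cdr3_nt = cdr3_mut_nt, cdr3_aa = cdr3_mut_aa,
        n_v_mut = n_v_mut, shm_nt_pct_true = 100 * n_v_mut / vlen,
        productive = productive, stringsAsFactors = FALSE)

      # mRNA molecules and UMIs
      n_mrna <- config$mrna_min + rpois(1, config$mrna_mean - config$mrna_min)
      for (mi in seq_len(n_mrna)) {
        mol_n <- mol_n + 1L
        umi <- NA_character_
        if (config$umi_length > 0) {
          collide <- length(umi_pool) > 0 && any(umi_cell != ci) &&
            runif(1) < config$umi_collision_rate
          if (collide) {
            umi <- sample(umi_pool[umi_cell != ci], 1)
          } else {
            repeat {
              umi <- random_nt(config$umi_length)
              if (!umi %in% umi_pool) break
            }
          }
          umi_pool <- c(umi_pool, umi); umi_cell <- c(umi_cell, ci)
        }
        mols[[mol_n]] <- data.frame(molecule_id = mol_n, cell_id = ci,
                                    umi = umi, stringsAsFactors = FALSE)
        n_dup <- config$pcr_duplicates_min +
          rpois(1, config$pcr_duplicates_mean - config$pcr_duplicates_min)
        for (ri in seq_len(n_dup)) {
          len <- nchar(transcript)
          pe <- which(runif(len) < config$pcr_error_rate)
          nt_read <- mutate_bases(transcript, pe)
          q <- pmin(41L, pmax(2L, as.integer(round(
            rnorm(len, config$phred_mean, config$phred_sd)))))
          se <- if (config$miscalls) which(runif(len) < 10^(-q / 10)) else integer(0)
          nt_read <- mutate_bases(nt_read, se)
          reads[[length(reads) + 1L]] <- data.frame(
            molecule_id = mol_n, cell_id = ci, umi = umi, nt = nt_read,
            qual = int_to_phred(q), n_pcr_errors = length(pe),
            n_seq_errors = length(se), stringsAsFactors = FALSE)
        }
      }
    }
    cells <- do.call(rbind, cells)
    molecules <- do.call(rbind, mols)
    reads <- do.call(rbind, reads)
    ord <- sample(nrow(reads))
    reads <- reads[ord, , drop = FALSE]
    reads$read_id <- sprintf("read%06d", seq_len(nrow(reads)))
    rownames(reads) <- NULL
    v_subs <- if (length(vl <- Filter(Negate(is.null), vsubs)))
      do.call(rbind, vl) else
      data.frame(cell_id = integer(0), v_call = character(0),
                 imgt_pos = integer(0), germline_aa = character(0),
                 observed_aa = character(0), stringsAsFactors = FALSE)
    records <- new_records(read_id = reads$read_id, nt = reads$nt,
                           qual = reads$qual, umi = reads$umi)
    list(records = records,
         truth = list(cells = cells, molecules = molecules,
                      reads = reads[, c("read_id", "molecule_id", "cell_id",
                                        "umi", "n_pcr_errors", "n_seq_errors")],
                      v_subs = v_subs),
         germline = germ, config = config)
  })
}

#' Simulate annotated clone representatives with planted substitutions
#'
#' Generates representative-level data for substitution-profile work without
#' running the full read-level pipeline: each representative observes every
#' IMGT position of its germline V, and amino-acid substitutions are planted
#' at the requested positions in a known fraction of representatives.
#'
#' @param germline `abrep_germline` reference.
#' @param v_call Germline V allele to build on.
#' @param n Number of representatives.
#' @param subs `data.frame(imgt_pos, observed_aa, fraction)` of substitutions
#'   to plant; `fraction` is the proportion of representatives carrying each.
#' @param seed Integer seed.
#' @param deterministic If `TRUE`, exactly `round(fraction * n)`
#'   representatives carry each substitution; otherwise carriage is Bernoulli.
#' @return An annotated-transcript style `data.frame` with `v_call`,
#'   `shm_nt_pct`, and list-columns `shm_aa_subs` and `numbering`, suitable
#'   for [build_gssp()].
#' @export
simulate_clone_representatives <- function(germline, v_call, n,
                                           subs = NULL, seed = 1,
                                           deterministic = TRUE) {
  v <- germline_get(germline, v_call)
  germ_aa <- chars(translate_nt(v$ungapped_nt))
  aamap <- imgt_aa_pos(v)[seq(1, nchar(v$ungapped_nt), by = 3)]
  base_num <- data.frame(position = as.character(aamap), residue = germ_aa,
                         aa_pos = seq_along(germ_aa), stringsAsFactors = FALSE)
  with_seed(seed, {
    carry <- matrix(FALSE, nrow = n, ncol = if (is.null(subs)) 0 else nrow(subs))
    if (!is.null(subs)) {
      for (k in seq_len(nrow(subs))) {
        if (deterministic) {
          m <- round(subs$fraction[k] * n)
          if (m > 0) carry[seq_len(m), k] <- TRUE
        } else {
          carry[, k] <- runif(n) < subs$fraction[k]
        }
      }
    }
    rows <- lapply(seq_len(n), function(i) {
      num <- base_num
      sh <- data.frame(imgt_pos = integer(0), germline_aa = character(0),
                       observed_aa = character(0), stringsAsFactors = FALSE)
      if (!is.null(subs)) {
        for (k in which(carry[i, ])) {
          p <- subs$imgt_pos[k]
          row <- which(aamap == p)
          if (!length(row)) stop("imgt_pos ", p, " not present in ", v_call)
          num$residue[row] <- subs$observed_aa[k]
          sh <- rbind(sh, data.frame(imgt_pos = p,
                                     germline_aa = germ_aa[row],
                                     observed_aa = subs$observed_aa[k],
                                     stringsAsFactors = FALSE))
        }
      }
      list(num = num, sh = sh)
    })
    out <- data.frame(read_id = sprintf("rep%05d", seq_len(n)),
                      v_call = v_call,
                      shm_nt_pct = vapply(rows, function(r) 3 * nrow(r$sh) /
                                            nchar(v$ungapped_nt) * 100, numeric(1)),
                      stringsAsFactors = FALSE)
    out$shm_aa_subs <- lapply(rows, `[[`, "sh")
    out$numbering <- lapply(rows, function(r) list(imgt = r$num))
    out
  })
}
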