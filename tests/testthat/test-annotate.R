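test_that("expected_errors matches the closed form and a brute-force sum", {
  expect_equal(expected_errors(rep(20L, 100)), 1.0)
  expect_equal(expected_errors(rep(10L, 10)), 1.0)
  withr::with_seed(1, {
    q <- sample(2:41, 250, replace = TRUE)
    brute <- 0
    for (qi in q) brute <- brute + 10^(-qi / 10)
    expect_equal(expected_errors(q), brute)
    expect_equal(expected_errors(int_to_phred(q)), brute)
  })
  expect_error(expected_errors(c(10L, -1L)), "negative")
  expect_error(expected_errors(integer(0)), "empty")
})

test_that("qc_filter applies the length and expected-miscall thresholds", {
  recs <- records_of(c(random_dna(299), random_dna(300), random_dna(2100),
                       random_dna(2100)))
  recs$qual <- c(strrep("I", 299),                    # Q40, short
                 strrep("I", 300),                    # Q40, fine
                 strrep("5", 2100),                   # Q20 x 2100 -> EE = 21
                 strrep("I", 2100))                   # Q40 -> EE = 0.21
  out <- qc_filter(recs, qc_thresholds())
  expect_equal(out$kept$read_id, c("r002", "r004"))
  expect_equal(out$rejected$reason, c("length", "expected_errors"))
})

test_that("read pairs merge on their best ungapped overlap", {
  # construct: r1 tail of 8 overlaps r2 head; r2 extends by 4 nt
  r1 <- list(read_id = "p1", nt = "ACGTACGTACGT", qual = strrep("I", 12))
  ext <- "CCCC"
  r2nt <- abrep::revcomp(paste0(substr(r1$nt, 5, 12), ext))
  r2 <- list(read_id = "p2", nt = r2nt, qual = strrep("I", nchar(r2nt)))
  m <- merge_read_pair(r1, r2, min_overlap = 5)
  expect_equal(m$record$nt, paste0(r1$nt, ext))
  expect_equal(m$overlap, 8L)
  expect_equal(m$matches, 8L)
  # identical full-length reads merge to themselves
  r3 <- list(read_id = "p3", nt = r1$nt, qual = r1$qual)
  r4 <- list(read_id = "p4", nt = abrep::revcomp(r1$nt), qual = r1$qual)
  m2 <- merge_read_pair(r3, r4, min_overlap = 5)
  expect_equal(m2$record$nt, r1$nt)
  # unrelated 50-mers are rejected: verify against an exhaustive overlap scan
  withr::with_seed(8, {
    for (k in 1:10) {
      a <- random_dna(50); b <- random_dna(50)
      res <- merge_read_pair(list(read_id = "x", nt = a, qual = strrep("I", 50)),
                             list(read_id = "y", nt = b, qual = strrep("I", 50)),
                             min_overlap = 10)
      bc <- abrep::revcomp(b)
      best_s <- -Inf; best_id <- 0
      for (o in 10:50) {  # same selection rule, naively recomputed
        mm <- sum(strsplit(substr(a, 51 - o, 50), "")[[1]] ==
                    strsplit(substr(bc, 1, o), "")[[1]])
        s <- 2 * mm - o
        if (s >= best_s) { best_s <- s; best_id <- mm / o }
      }
      if (best_id < 0.8) expect_null(res$record) else expect_false(is.null(res$record))
    }
  })
})

test_that("V/J assignment recovers exact germline concatenations", {
  g <- toy_germline(1)
  v <- g[g$allele_name == "IGHV-T2*01", ]
  j <- g[g$allele_name == "IGHJ-T1*01", ]
  nt <- paste0(v$ungapped_nt, j$ungapped_nt)
  res <- assign_vdj(list(nt = nt), g)
  expect_equal(res$v_call, "IGHV-T2*01")
  expect_equal(res$j_call, "IGHJ-T1*01")
  expect_equal(res$v$identity, 1.0)
  expect_equal(nrow(res$v$mismatches), 0L)
  # three substitutions in V: same call, three recorded mismatch positions
  b <- strsplit(nt, "")[[1]]
  pos <- c(30L, 101L, 200L)
  b[pos] <- vapply(b[pos], function(x) setdiff(c("A","C","G","T"), x)[1], "")
  res3 <- assign_vdj(list(nt = paste(b, collapse = "")), g)
  expect_equal(res3$v_call, "IGHV-T2*01")
  expect_equal(sort(res3$v$mismatches$ref_pos), pos)
  # a scrambled sequence is unassignable
  scr <- paste(sample(b), collapse = "")
  expect_true(is.na(assign_vdj(list(nt = scr), g)$v_call))
})

test_that("CDR3 extraction finds the junction between Cys104 and the J anchor", {
  g <- toy_germline(1)
  v <- g[g$allele_name == "IGHV-T1*01", ]
  # junction designed to read ...TGT | GCGAGAGACTAC | TGGGGCCAAGGA...
  j_anchor_on <- substr(abrep:::.TOY_J[["IGHJ-T1*01"]], 10, 42)  # from the W codon
  nt <- paste0(v$ungapped_nt, "GCGAGAGACTAC", j_anchor_on)
  res <- assign_vdj(list(nt = nt), g)
  cdr3 <- extract_cdr3(nt, res$v, res$j, v, chain = "heavy")
  expect_equal(cdr3$cdr3_aa, "ARDY")
  expect_equal(cdr3$cdr3_nt, "GCGAGAGACTAC")
  # mutating the anchor Cys codon removes the CDR3
  b <- strsplit(nt, "")[[1]]
  b[v$cys104_start] <- "C"; b[v$cys104_start + 1] <- "G"  # TGT -> CGT (Arg)
  nt_mut <- paste(b, collapse = "")
  res2 <- assign_vdj(list(nt = nt_mut), g)
  expect_null(extract_cdr3(nt_mut, res2$v, res2$j, v, chain = "heavy"))
})

test_that("annotation of a noise-free repertoire recovers all ground truth", {
  cfg <- sim_config(seed = 31, n_cells = 60, shm_rate = 0, pcr_error_rate = 0,
                    mrna_mean = 1, mrna_min = 1, pcr_duplicates_mean = 1,
                    pcr_duplicates_min = 1, miscalls = FALSE, umi_length = 0)
  sim <- simulate_repertoire(cfg)
  ann <- annotate_repertoire(sim$records, sim$germline)
  tr <- merge(merge(ann, sim$truth$reads, by = "read_id"),
              sim$truth$cells, by = "cell_id", suffixes = c("", ".true"))
  prod <- tr$productive.true
  expect_true(all(tr$v_call[prod] == tr$v_call.true[prod]))
  expect_true(all(tr$j_call[prod] == tr$j_call.true[prod]))
  expect_true(all(tr$cdr3_aa[prod] == tr$cdr3_aa.true[prod]))
  expect_true(all(tr$shm_nt_pct[prod] == 0))
  expect_true(all(tr$productive[prod]))
  # isotype equals the simulated CH1 gene
  iso_true <- c(M = "IgM", G = "IgG", A = "IgA")[substr(tr$c_call, 4, 4)]
  expect_true(all(tr$isotype[prod] == iso_true[prod]))
})

test_that("SHM percentage and amino-acid substitutions are computed per IMGT position", {
  g <- toy_germline(1)
  v <- g[g$allele_name == "IGHV-T3*01", ]
  j <- g[g$allele_name == "IGHJ-T1*01", ]
  nt <- paste0(v$ungapped_nt, j$ungapped_nt)
  # plant 6 nt substitutions at codon starts of V codons 10, 20, 30, 40, 50, 60
  b <- strsplit(nt, "")[[1]]
  codons <- c(10L, 20L, 30L, 40L, 50L, 60L)
  for (a in codons) {
    i <- 3 * (a - 1) + 1
    b[i] <- setdiff(c("A", "C", "G", "T"), b[i])[1]
  }
  res <- assign_vdj(list(nt = paste(b, collapse = "")), g)
  shm <- compute_shm(res$v, v)
  expect_equal(shm$shm_nt_pct, 100 * 6 / nchar(v$ungapped_nt))
  aamap <- ceiling(v$imgt_nt_pos[[1]] / 3)
  expected_pos <- aamap[3 * (codons - 1) + 1]
  # nonsynonymous changes appear at the right IMGT positions
  expect_true(all(shm$shm_aa_subs$imgt_pos %in% expected_pos))
  # identical sequence: zero percent, no substitutions
  res0 <- assign_vdj(list(nt = nt), g)
  shm0 <- compute_shm(res0$v, v)
  expect_equal(shm0$shm_nt_pct, 0)
  expect_equal(nrow(shm0$shm_aa_subs), 0L)
})

test_that("productivity detection flags frameshifts and stop codons", {
  cfg <- sim_config(seed = 33, n_cells = 1, shm_rate = 0, pcr_error_rate = 0,
                    mrna_mean = 1, mrna_min = 1, pcr_duplicates_mean = 1,
                    pcr_duplicates_min = 1, miscalls = FALSE, umi_length = 0)
  sim <- simulate_repertoire(cfg)
  g <- sim$germline
  nt <- sim$records$nt[1]
  ann <- function(s) {
    res <- assign_vdj(list(nt = s), g)
    v <- g[g$allele_name == res$v_call, ]
    cdr3 <- extract_cdr3(s, res$v, res$j, v, chain = "heavy")
    detect_frameshift_stop(s, res$v, cdr3, res$j)
  }
  expect_true(ann(nt))
  # single-nt deletion in framework 3 (upstream of the Cys codon)
  del <- paste0(substr(nt, 1, 200), substr(nt, 202, nchar(nt)))
  expect_false(ann(del))
  # premature stop codon planted at a codon boundary in V
  b <- strsplit(nt, "")[[1]]
  b[151:153] <- c("T", "A", "A")
  expect_false(ann(paste(b, collapse = "")))
})

test_that("IMGT numbering reproduces the germline map and the CDR3 fill rule", {
  g <- toy_germline(1)
  v <- g[g$allele_name == "IGHV-T1*01", ]
  # 13-residue CDR3: 39 junction nt between the Cys codon and the J anchor
  withr::with_seed(2, jx <- random_dna(39 - 9))
  jfull <- abrep:::.TOY_J[["IGHJ-T1*01"]]
  nt <- paste0(v$ungapped_nt, jx, jfull)   # 30 N nt + 9 nt J head = 13 codons
  res <- assign_vdj(list(nt = nt), g)
  cdr3 <- extract_cdr3(nt, res$v, res$j, v, chain = "heavy")
  expect_equal(nchar(cdr3$cdr3_aa), 13L)
  num <- number_positions(nt, res$v, v, cdr3, res$j, scheme = "imgt")
  # V region: numbering equals the germline's own position map
  germ_aa <- strsplit(abrep:::translate_nt(v$ungapped_nt), "")[[1]]
  aamap <- ceiling(v$imgt_nt_pos[[1]] / 3)[seq(1, nchar(v$ungapped_nt), 3)]
  vpart <- num[match(as.character(aamap), num$position), ]
  expect_equal(vpart$residue, germ_aa)
  # CDR3: positions 105..117, no insertion codes
  expect_true(all(as.character(105:117) %in% num$position))
  expect_false(any(grepl("\\.", num$position)))
  # J anchor Trp at 118
  expect_equal(num$residue[num$position == "118"], "W")
  # Kabat scheme: residue at Kabat 52 equals the residue at IMGT 54
  tab <- default_numbering_table()
  kab <- number_positions(nt, res$v, v, cdr3, res$j, scheme = "kabat")
  imgt_of_k52 <- tab$imgt[tab$kabat == "52"]
  expect_equal(kab$residue[kab$position == "52"],
               num$residue[num$position == imgt_of_k52])
})

test_that("longer CDR3 junctions receive IMGT insertion codes", {
  labels <- abrep:::imgt_cdr3_labels(15L)
  expect_equal(labels, c(as.character(105:111), "111.1", "112.1",
                         as.character(112:117)))
  expect_equal(abrep:::imgt_cdr3_labels(4L), c("105", "106", "116", "117"))
})

test_that("the expectation statistic is monotone decreasing in score", {
  s <- seq(10, 100, by = 10)
  ev <- evalue_like(s, 300, 400)
  expect_true(all(diff(ev) < 0))
})

test_that("isotype assignment needs a significant CH1 hit", {
  g <- toy_germline(1)
  ch1 <- g[g$allele_name == "IGHG-TOY*01", ]$ungapped_nt
  v <- g[g$allele_name == "IGHV-T1*01", ]$ungapped_nt
  expect_equal(assign_isotype(paste0(v, ch1), g), "IgG")
  expect_equal(assign_isotype(v, g, after = nchar(v)), "unknown")
  # two mismatches still pass the threshold
  b <- strsplit(ch1, "")[[1]]
  b[c(5, 20)] <- vapply(b[c(5, 20)], function(x)
    setdiff(c("A", "C", "G", "T"), x)[1], "")
  expect_equal(assign_isotype(paste0(v, paste(b, collapse = "")), g), "IgG")
})
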