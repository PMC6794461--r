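# minimal annotated-transcript table for matching tests
ptx <- function(v_call, cdr3_aa, isotype = "IgM", numbering = NULL) {
  df <- data.frame(read_id = sprintf("t%03d", seq_along(v_call)),
                   nt = NA_character_, v_call = v_call, cdr3_aa = cdr3_aa,
                   isotype = isotype, stringsAsFactors = FALSE)
  df$numbering <- numbering %||% rep(list(NULL), nrow(df))
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("motifs compile to anchored patterns and reject malformed input", {
  rx <- compile_motif("X-X-[AFILMYWV]-[EQ]-X")
  expect_equal(attr(rx, "n_slots"), 5L)
  expect_true(grepl(rx, "QQYEF"))     # Y in class, E in class
  expect_false(grepl(rx, "QQGGF"))    # G not in the third-slot class
  expect_false(grepl(rx, "QQYEFF"))   # anchored: length must match
  expect_error(compile_motif("X--X"), "slot")
  expect_error(compile_motif("X-[AB1]-X"), "slot 2")
  expect_error(compile_motif("X-foo-X"), "slot 2")
})

test_that("CDR3 motif matching honours gene, isotype and length constraints", {
  q <- signature_query("cdr3", motif = "X-X-[AFILMYWV]-[EQ]-X",
                       gene = "IGKV-T1", cdr3_length = 5)
  tx <- ptx(c("IGKV-T1*01", "IGKV-T1*01", "IGKV-T2*01", "IGKV-T1*01"),
            c("QQYEF", "QQGGF", "QQYEF", "QQYEFX"))
  expect_equal(match_cdr3(q, tx), c(TRUE, FALSE, FALSE, FALSE))
  # allele-level constraint
  q2 <- signature_query("cdr3", motif = "X-X-[AFILMYWV]-[EQ]-X",
                        gene = "IGKV-T1*01")
  expect_equal(match_cdr3(q2, ptx("IGKV-T1*02", "QQYEF")), FALSE)
  # 6-residue CDR3 never matches a 5-slot query with cdr3_length = 5
  expect_false(match_cdr3(q, ptx("IGKV-T1*01", "QQYEEF")))
})

test_that("match_cdr3 agrees with a general-purpose regex oracle", {
  classes <- c("[AFILMYWV]", "[EQ]", "[ST]", "X", "A", "G", "F")
  withr::with_seed(77, {
    agree <- vapply(1:2000, function(k) {
      n <- sample(3:6, 1)
      slots <- sample(classes, n, replace = TRUE)
      motif <- paste(slots, collapse = "-")
      cdr3 <- random_aa(sample(3:6, 1))
      q <- signature_query("cdr3", motif = motif)
      got <- match_cdr3(q, ptx("IGHV-T1*01", cdr3))
      slots_rx <- gsub("^X$", "[A-Z]", slots)
      want <- grepl(paste0("^", paste(slots_rx, collapse = ""), "$"), cdr3)
      got == want
    }, logical(1))
    expect_true(all(agree))
  })
})

test_that("numbered-position constraints fail on unobserved positions", {
  g <- toy_germline(1)
  reps <- simulate_clone_representatives(
    g, "IGHV-T3*01", 1,
    subs = data.frame(imgt_pos = 54, observed_aa = "W", fraction = 1),
    seed = 31)
  # extend the numbering with the Kabat scheme via the translation table
  tab <- default_numbering_table()
  num <- reps$numbering[[1]]$imgt
  kab <- num
  kab$position <- tab$kabat[match(num$position, tab$imgt)]
  reps$numbering[[1]]$kabat <- kab[!is.na(kab$position), ]
  reps$isotype <- "IgM"; reps$cdr3_aa <- "ARDY"; reps$nt <- NA
  q <- signature_query("position", positions = data.frame(
    scheme = "kabat", position = "52", residues = "W",
    stringsAsFactors = FALSE), gene = "IGHV-T3")
  expect_true(match_position(q, reps))
  # wrong residue
  q2 <- signature_query("position", positions = data.frame(
    scheme = "kabat", position = "52", residues = "L",
    stringsAsFactors = FALSE))
  expect_false(match_position(q2, reps))
  # truncated transcript: position absent -> constraint fails
  reps_tr <- reps
  reps_tr$numbering[[1]]$kabat <-
    reps_tr$numbering[[1]]$kabat[reps_tr$numbering[[1]]$kabat$position != "52", ]
  expect_false(match_position(q, reps_tr))
})

test_that("sequence search ranks significant local alignments", {
  withr::with_seed(78, {
    db <- data.frame(read_id = sprintf("t%d", 1:20),
                     nt = vapply(1:20, function(i) random_dna(350), ""),
                     v_call = "IGHV-T1*01", stringsAsFactors = FALSE)
    q <- signature_query("sequence", query_seq = db$nt[7])
    hits <- match_sequence(q, db)
    expect_equal(hits$read_id[1], "t7")
    # 5% mismatched copy is still found
    b <- strsplit(db$nt[7], "")[[1]]
    at <- sample(350, 17)
    b[at] <- vapply(b[at], function(x) setdiff(c("A","C","G","T"), x)[1], "")
    q2 <- signature_query("sequence", query_seq = paste(b, collapse = ""))
    expect_true("t7" %in% match_sequence(q2, db)$read_id)
    # an unrelated random query matches nothing
    q3 <- signature_query("sequence", query_seq = random_dna(350))
    expect_equal(nrow(match_sequence(q3, db)), 0L)
  })
})

test_that("signature frequencies use the documented denominators", {
  tx <- ptx(c(rep("IGKV-T1*01", 100), rep("IGKV-T2*01", 900)),
            c(rep("QQYEF", 2), rep("AAAAA", 98), rep("CCCCC", 900)))
  q <- signature_query("cdr3", motif = "X-X-[AFILMYWV]-[EQ]-X",
                       gene = "IGKV-T1", cdr3_length = 5)
  row <- signature_frequency(q, tx)
  expect_equal(row$n_matched, 2L)
  expect_equal(row$n_denominator, 100L)
  expect_equal(row$frequency, 0.02)
  # whole-repertoire denominator on request
  row2 <- signature_frequency(q, tx, denominator = "all")
  expect_equal(row2$frequency, 2 / 1000)
  # a zero denominator reports an absent frequency, not zero
  q3 <- signature_query("cdr3", motif = "X-X-X-X-X", gene = "IGKV-T9")
  expect_true(is.na(signature_frequency(q3, tx)$frequency))
})

test_that("planted signature fractions are recovered exactly", {
  withr::with_seed(80, {
    n <- 400
    alph <- c("A","C","D","E","F","G","H","I","K","L",
              "M","N","P","Q","R","S","T","V","W")   # no Tyr: no chance hits
    cdr3 <- vapply(1:n, function(i) random_aa(5, alph), "")
    # plant the motif in exactly 3% of the gene's transcripts
    planted <- sample(n, 12)
    cdr3[planted] <- paste0("QQ", "Y", "E", "F")
    tx <- ptx(rep("IGKV-T1*01", n), cdr3)
    q <- signature_query("cdr3", motif = "X-X-[Y]-[E]-[F]", gene = "IGKV-T1")
    expect_equal(signature_frequency(q, tx)$frequency, 12 / 400)
  })
})

test_that("paired-chain prevalence multiplies whole-repertoire frequencies", {
  expect_equal(pairing_frequency(0.027, 0.00005), 1.4)
  expect_equal(pairing_frequency(0, 0.5), 0)
  expect_equal(pairing_frequency(0.01, 0.01), 100)
  expect_error(pairing_frequency(1.2, 0.5), "frequencies")
})

test_that("rarefaction CV is zero for uniform panels and exhaustive sampling", {
  curve <- rarefaction_cv(rep(0.03, 8), sizes = 1:8, n_repeats = 20, seed = 5)
  expect_equal(curve$cv, rep(0, 8))
  # i = n: every subset is the full panel
  f <- c(0.01, 0.05, 0.2, 0.002, 0.11)
  c2 <- rarefaction_cv(f, sizes = 5, n_repeats = 20, seed = 5)
  expect_equal(c2$cv, 0)
  expect_equal(c2$mean_freq, mean(f))
})

test_that("exhaustive rarefaction equals explicit subset enumeration", {
  f <- c(0.031, 0.012, 0.047, 0.025, 0.002, 0.038)  # printed 6-repertoire panel
  curve <- rarefaction_cv(f, sizes = 2, exhaustive = TRUE, seed = 1)
  sub_means <- apply(combn(6, 2), 2, function(ix) mean(f[ix]))  # all 15 subsets
  expect_equal(curve$n_repeats, 15L)
  expect_equal(curve$mean_freq, mean(sub_means))
  expect_equal(curve$cv, sd(sub_means) / mean(sub_means))
})

test_that("median CV does not increase with sampling size on iid panels", {
  withr::with_seed(90, {
    sizes <- c(2, 5, 10, 20, 35)
    cvs <- sapply(1:25, function(r) {
      f <- rgamma(35, shape = 2, rate = 60)  # iid per-repertoire frequencies
      rarefaction_cv(f, sizes, n_repeats = 20, seed = r)$cv
    })
    med <- apply(cvs, 1, median)
    expect_true(all(diff(med) <= 0))
  })
})

test_that("sampling sizes beyond the panel are an error", {
  expect_error(rarefaction_cv(c(0.1, 0.2), sizes = 3), "exceeds")
})
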