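# transcripts table builder for clonotype tests
tx_of <- function(v, j, cdr3_nt, abundance = 1L) {
  data.frame(read_id = sprintf("t%03d", seq_along(cdr3_nt)),
             nt = cdr3_nt, v_call = v, j_call = j, cdr3_nt = cdr3_nt,
             cdr3_aa = vapply(cdr3_nt, abrep:::translate_nt, "",
                              USE.NAMES = FALSE),
             abundance = abundance, stringsAsFactors = FALSE)
}

test_that("clones require shared V, J and CDR3 length", {
  tx <- tx_of("IGHV-T1*01", "IGHJ-T1*01",
              c("GCGAGAGACTAC", "GCGAGAGACTAC"))
  cl <- suppressMessages(cluster_clones(tx))
  expect_equal(length(unique(cl$clone_id)), 1L)
  expect_equal(sum(cl$is_representative), 1L)
  # same V/J but CDR3 lengths 4 vs 5 aa: two clones
  tx2 <- tx_of("IGHV-T1*01", "IGHJ-T1*01",
               c("GCGAGAGACTAC", "GCGAGAGACTACTGG"))
  cl2 <- suppressMessages(cluster_clones(tx2))
  expect_equal(length(unique(cl2$clone_id)), 2L)
  # allele differences within a gene do not split clones
  tx3 <- tx_of(c("IGHV-T1*01", "IGHV-T1*02"), "IGHJ-T1*01",
               rep("GCGAGAGACTAC", 2))
  cl3 <- suppressMessages(cluster_clones(tx3))
  expect_equal(length(unique(cl3$clone_id)), 1L)
  # transcripts without a CDR3 are excluded with a message
  tx4 <- tx_of("IGHV-T1*01", "IGHJ-T1*01", c("GCGAGAGACTAC", ""))
  expect_message(cl4 <- cluster_clones(tx4), "excluded")
  expect_true(is.na(cl4$clone_id[2]))
})

test_that("clonal lineages are recovered from mutated CDR3s", {
  skip_if_not_installed("mclust")
  withr::with_seed(71, {
    n_clones <- 25
    rows <- list()
    for (k in seq_len(n_clones)) {
      len <- 3 * sample(5:8, 1)
      founder <- random_dna(len)
      v <- sample(c("IGHV-T1*01", "IGHV-T2*01", "IGHV-T3*01"), 1)
      j <- sample(c("IGHJ-T1*01", "IGHJ-T2*01"), 1)
      # expanded founder plus descendants mutated <= 5% of the CDR3
      rows[[length(rows) + 1]] <- data.frame(
        truth = k, v_call = v, j_call = j, cdr3_nt = founder,
        abundance = 5L, stringsAsFactors = FALSE)
      for (m in seq_len(sample(1:5, 1))) {
        b <- strsplit(founder, "")[[1]]
        nmut <- sample(0:max(1, floor(0.05 * len)), 1)
        if (nmut > 0) {
          at <- sample(len, nmut)
          b[at] <- sample(c("A", "C", "G", "T"), nmut, TRUE)
        }
        rows[[length(rows) + 1]] <- data.frame(
          truth = k, v_call = v, j_call = j,
          cdr3_nt = paste(b, collapse = ""), abundance = 1L,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    tx <- tx_of(df$v_call, df$j_call, df$cdr3_nt, abundance = df$abundance)
    tx$read_id <- sprintf("t%04d", seq_len(nrow(tx)))
    cl <- suppressMessages(cluster_clones(tx))
    ari <- mclust::adjustedRandIndex(df$truth, cl$clone_id)
    expect_gte(ari, 0.95)
  })
})

test_that("GSSP recovers planted substitution frequencies", {
  g <- toy_germline(1)
  subs <- data.frame(imgt_pos = 54, observed_aa = "N", fraction = 0.10)
  reps <- simulate_clone_representatives(g, "IGHV-T1*01", 200, subs,
                                         seed = 3, deterministic = TRUE)
  gssp <- build_gssp(reps, "IGHV-T1", min_clones = 100)
  expect_s3_class(gssp, "abrep_gssp")
  expect_equal(gssp$n_clones, 200L)
  i <- which(gssp$freq$position == 54 & gssp$freq$aa == "N")
  expect_equal(gssp$freq$freq[i], 0.10)
  expect_equal(gssp$freq$coverage[i], 200L)
  # stochastic planting lands within 3 binomial standard errors
  reps2 <- simulate_clone_representatives(g, "IGHV-T1*01", 600, subs,
                                          seed = 4, deterministic = FALSE)
  gssp2 <- build_gssp(reps2, "IGHV-T1", min_clones = 100)
  f2 <- gssp2$freq$freq[gssp2$freq$position == 54 & gssp2$freq$aa == "N"]
  expect_lt(abs(f2 - 0.10), 3 * sqrt(0.1 * 0.9 / 600))
})

test_that("GSSPs are withheld below the minimum clone count", {
  g <- toy_germline(1)
  reps <- simulate_clone_representatives(g, "IGHV-T2*01", 99, seed = 5)
  expect_message(out <- build_gssp(reps, "IGHV-T2", min_clones = 100),
                 "withheld")
  expect_null(out)
  reps100 <- simulate_clone_representatives(g, "IGHV-T2*01", 100, seed = 5)
  expect_s3_class(build_gssp(reps100, "IGHV-T2", min_clones = 100),
                  "abrep_gssp")
  expect_error(build_gssp(reps100, "IGHV-T9"), "no representatives")
})

test_that("germline-identical representatives give an all-zero profile", {
  g <- toy_germline(1)
  reps <- simulate_clone_representatives(g, "IGHV-T3*01", 120, seed = 6)
  gssp <- build_gssp(reps, "IGHV-T3", min_clones = 100)
  expect_equal(nrow(gssp$freq), 0L)
})

test_that("per_mutated normalisation sums to one at mutated positions", {
  g <- toy_germline(1)
  subs <- data.frame(imgt_pos = c(40, 40, 70),
                     observed_aa = c("N", "K", "R"),
                     fraction = c(0.10, 0.05, 0.20))
  reps <- simulate_clone_representatives(g, "IGHV-T1*01", 200, subs, seed = 7)
  gssp <- build_gssp(reps, "IGHV-T1", min_clones = 100, mode = "per_mutated")
  for (p in unique(gssp$freq$position)) {
    expect_equal(sum(gssp$freq$freq[gssp$freq$position == p]), 1.0)
  }
})

test_that("profile concordance behaves like a correlation", {
  g <- toy_germline(1)
  subs <- data.frame(imgt_pos = c(30, 54, 70, 90),
                     observed_aa = c("K", "N", "R", "F"),
                     fraction = c(0.05, 0.12, 0.30, 0.02))
  a <- build_gssp(simulate_clone_representatives(g, "IGHV-T1*01", 1000, subs,
                                                 seed = 11, deterministic = FALSE),
                  "IGHV-T1")
  expect_equal(compare_gssp(a, a), 1.0)
  b <- build_gssp(simulate_clone_representatives(g, "IGHV-T1*01", 1000, subs,
                                                 seed = 12, deterministic = FALSE),
                  "IGHV-T1")
  expect_gte(compare_gssp(a, b), 0.9)
  # permuting the cells of one profile destroys the concordance
  perm <- a
  withr::with_seed(13, perm$freq$freq <- sample(perm$freq$freq))
  r_perm <- compare_gssp(a, perm)
  expect_lt(abs(r_perm), 0.9)
})

test_that("mutation rarity applies the (1 - frequency) formula exactly", {
  g <- toy_germline(1)
  v <- g[g$allele_name == "IGHV-T1*01", ]
  subs <- data.frame(imgt_pos = c(54, 70), observed_aa = c("N", "R"),
                     fraction = c(0.004, 1.0))
  reps <- simulate_clone_representatives(g, "IGHV-T1*01", 1000, subs, seed = 8)
  gssp <- build_gssp(reps, "IGHV-T1")
  db <- list("IGHV-T1" = gssp)
  # build a query sequence carrying both substitutions
  aamap <- ceiling(v$imgt_nt_pos[[1]] / 3)[seq(1, nchar(v$ungapped_nt), 3)]
  b <- strsplit(v$ungapped_nt, "")[[1]]
  i54 <- 3 * (which(aamap == 54) - 1) + 1
  i70 <- 3 * (which(aamap == 70) - 1) + 1
  b[i54:(i54 + 2)] <- c("A", "A", "C")  # Asn
  b[i70:(i70 + 2)] <- c("A", "G", "A")  # Arg
  res <- mutation_rarity(paste(b, collapse = ""), "IGHV-T1*01", db, g)
  expect_equal(nrow(res), 2L)
  r54 <- res[res$position == 54, ]
  expect_equal(r54$frequency, 0.004)
  expect_equal(r54$rarity, 99.6)
  expect_true(r54$is_rare)
  r70 <- res[res$position == 70, ]
  expect_equal(r70$rarity, 0)
  expect_false(r70$is_rare)
  # the identity rarity + 100 * frequency = 100 holds for every cell
  expect_equal(res$rarity + 100 * res$frequency, rep(100, nrow(res)))
  # germline-identical input yields no mutations
  res0 <- mutation_rarity(v$ungapped_nt, "IGHV-T1*01", db, g)
  expect_equal(nrow(res0), 0L)
  expect_error(mutation_rarity(v$ungapped_nt, "IGHV-T4*01", db, g), "IGHV-T4")
})

test_that("GSSPs round-trip through the TSV + JSON serialisation", {
  g <- toy_germline(1)
  subs <- data.frame(imgt_pos = 54, observed_aa = "N", fraction = 0.10)
  gssp <- build_gssp(simulate_clone_representatives(g, "IGHV-T1*01", 150, subs,
                                                    seed = 9),
                     "IGHV-T1")
  tf <- tempfile(fileext = ".tsv")
  write_gssp(gssp, tf)
  back <- read_gssp(tf)
  expect_equal(back$v_gene, gssp$v_gene)
  expect_equal(back$n_clones, gssp$n_clones)
  expect_equal(back$normalization_mode, gssp$normalization_mode)
  expect_equal(back$freq$freq, gssp$freq$freq)
  expect_equal(unname(back$coverage), unname(gssp$coverage))
})
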