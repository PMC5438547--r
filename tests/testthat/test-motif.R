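jaspar_fixture <- system.file("extdata", "example_motifs.jaspar",
                              package = "tstvreg")

test_that("JASPAR flat files parse and round-trip", {
  pfm <- read_jaspar(jaspar_fixture)
  expect_equal(unique(pfm$motif_id), c("MA0001.1", "MA0002.1"))
  dims <- pfm |> dplyr::count(motif_id)
  expect_equal(dims$n, c(4 * 5, 4 * 6))
  # spot-check a count against the file
  expect_equal(
    pfm$count[pfm$motif_id == "MA0001.1" & pfm$position == 1 & pfm$base == "T"],
    17
  )

  f <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pfm, f)
  expect_equal(read_jaspar(f), pfm)

  empty <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(character(0), empty)
  expect_equal(nrow(read_jaspar(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 X", "A [1 2]", "C [1 2]", "G [1 2]"), bad)
  expect_error(read_jaspar(bad), class = "tstv_error_parse")
  bad2 <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 X", "A [1 2]", "C [1 2]", "G [1 2]", "T [1]"), bad2)
  expect_error(read_jaspar(bad2), class = "tstv_error_parse")
})

test_that("PSSM scores, information content, and consensus follow the log-odds formulas", {
  # hand-evaluated worked example: column (A:8, C:0, G:0, T:0), pseudocount 0.1
  one <- pfm_from_matrix(matrix(c(8, 0, 0, 0), 4, 1))
  p1 <- pfm_to_pssm(one)
  expect_equal(p1$freq[p1$base == "A"], 8.1 / 8.4, tolerance = 1e-12)
  expect_equal(p1$score[p1$base == "A"], log2((8.1 / 8.4) / 0.25),
               tolerance = 1e-12)

  # uniform column: all scores 0, ic 0
  u <- pfm_to_pssm(pfm_from_matrix(matrix(5, 4, 1)))
  expect_equal(u$score, rep(0, 4))
  expect_equal(u$ic, rep(0, 4))

  # ic bounds and permutation invariance over random columns
  withr::with_seed(42, {
    for (i in 1:20) {
      counts <- rmultinom(1, 60, runif(4))[, 1]
      ic1 <- pfm_to_pssm(pfm_from_matrix(matrix(counts, 4, 1)))$ic[1]
      ic2 <- pfm_to_pssm(pfm_from_matrix(matrix(sample(counts), 4, 1)))$ic[1]
      expect_true(ic1 >= 0 && ic1 <= 2)
      expect_equal(ic1, ic2, tolerance = 1e-12)
    }
  })

  # consensus ties break in A < C < G < T order
  tie <- pfm_to_pssm(pfm_from_matrix(matrix(c(3, 3, 0, 0), 4, 1)))
  expect_equal(tie$base[tie$consensus], "A")

  expect_error(pfm_to_pssm(one, pseudocount = -1),
               class = "tstv_error_argument")
})

test_that("sequence scoring is additive and maximal at the consensus", {
  pssm <- pfm_to_pssm(read_jaspar(jaspar_fixture))
  m <- dplyr::filter(pssm, motif_id == "MA0001.1")
  cons <- pssm_consensus(m)$consensus
  s_cons <- score_sequence(m, cons)

  withr::with_seed(10, {
    for (i in 1:10) {
      mut <- cons
      pos <- sample(nchar(cons), 1)
      newb <- sample(setdiff(DNA_BASES, substr(cons, pos, pos)), 1)
      substr(mut, pos, pos) <- newb
      # additivity: the total changes by exactly the column difference
      col_delta <- m$score[m$position == pos & m$base == newb] -
        m$score[m$position == pos & m$base == substr(cons, pos, pos)]
      expect_equal(score_sequence(m, mut) - s_cons, col_delta,
                   tolerance = 1e-12)
      expect_lte(score_sequence(m, mut), s_cons)
    }
  })

  # brute force: consensus attains the maximum over all 4^L sequences
  score_mat <- matrix(m$score, nrow = 4) # rows A,C,G,T; cols positions
  L <- ncol(score_mat)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  all_scores <- score_mat[cbind(as.vector(grid),
                                rep(seq_len(L), each = nrow(grid)))]
  all_scores <- rowSums(matrix(all_scores, nrow = nrow(grid)))
  expect_equal(max(all_scores), s_cons, tolerance = 1e-12)

  expect_error(score_sequence(m, "ACG"), class = "tstv_error_argument")
})

test_that("mutation enumeration yields 6 records per position, 2 Ts : 4 Tv", {
  pssm <- pfm_to_pssm(read_jaspar(jaspar_fixture))
  rec <- enumerate_mutation_scores(pssm)
  lens <- c(MA0001.1 = 5, MA0002.1 = 6)
  expect_equal(nrow(rec), sum(6 * lens))
  counts <- rec |> dplyr::count(motif_id, klass)
  expect_equal(counts$n[counts$klass == "TS"], unname(2 * lens))
  expect_equal(counts$n[counts$klass == "TV"], unname(4 * lens))

  # normalized position: 0 at the edges, 1 at the center (odd length)
  r1 <- dplyr::filter(rec, motif_id == "MA0001.1")
  expect_equal(unique(r1$norm_position[r1$position == 0]), 0)
  expect_equal(unique(r1$norm_position[r1$position == 4]), 0)
  expect_equal(unique(r1$norm_position[r1$position == 2]), 1)

  # uniform column: all 6 deltas are 0
  u <- pfm_to_pssm(pfm_from_matrix(matrix(5, 4, 3)))
  expect_equal(enumerate_mutation_scores(u)$delta, rep(0, 18))

  # deltas are invariant to adding a constant to a PSSM column
  shifted <- pssm
  shifted$score[shifted$position == 2] <- shifted$score[shifted$position == 2] + 3
  expect_equal(enumerate_mutation_scores(shifted)$delta, rec$delta)
})

test_that("stratified tests use the stated bin counts and flag untestable bins", {
  pssm <- pfm_to_pssm(gen_motif_library(20, seed = 6))
  rec <- enumerate_mutation_scores(pssm)
  pos_t <- stratified_ts_tv_test(rec, "norm_position")
  ic_t <- stratified_ts_tv_test(rec, "ic")
  expect_equal(nrow(pos_t), 11L)
  expect_equal(nrow(ic_t), 20L)
  expect_equal(pos_t$alpha_bonferroni[1], 0.05 / 11)
  expect_equal(ic_t$alpha_bonferroni[1], 0.05 / 20)
  expect_true(all(is.na(pos_t$p.value[!pos_t$testable])))
  # bin totals conserve the records
  expect_equal(sum(pos_t$n_ts + pos_t$n_tv), nrow(rec))

  expect_error(stratified_ts_tv_test(rec[0, ], "ic"),
               class = "tstv_error_argument")
})

test_that("planted Tv excess is detected where planted", {
  # records whose TV deltas are stochastically larger only at high IC
  withr::with_seed(13, {
    n <- 4000
    rec <- tibble::tibble(
      motif_id = "S1",
      position = 0L,
      norm_position = runif(n),
      ic = runif(n, 0, 2),
      b1 = "A", b2 = "C",
      klass = sample(c("TS", "TV"), n, replace = TRUE, prob = c(1, 2) / 3)
    )
    boost <- ifelse(rec$klass == "TV" & rec$ic > 1.5, 1.0, 0)
    rec$delta <- abs(rnorm(n, 1 + boost, 0.5))
    out <- stratified_ts_tv_test(rec, "ic", n_bins = 4)
    expect_true(all(out$p.value[4] < 0.001)) # planted bin (1.5, 2]
    expect_true(all(out$p.value[1:2] > 0.001)) # null bins
    expect_gt(out$mean_diff[4], 0.5)
  })
})
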