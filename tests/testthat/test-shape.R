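test_that("shape tables are validated and round-trip through TSV", {
  tb <- gen_shape_table(3)
  expect_equal(nrow(validate_shape_table(tb)), 1024L)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_shape_table(tb, f)
  tb2 <- read_shape_table(f)
  expect_equal(tb2, validate_shape_table(tb), tolerance = 1e-12)

  expect_error(validate_shape_table(tb[-1, ]),
               class = "tstv_error_table_format") # 1023 rows
  expect_error(validate_shape_table(dplyr::bind_rows(tb, tb[1, ])),
               class = "tstv_error_table_format") # duplicate
  bad <- tb; bad$mgw[5] <- NA
  expect_error(validate_shape_table(bad), class = "tstv_error_table_format")
})

test_that("shape profiles match a naive sliding-window oracle", {
  tb <- gen_shape_table(11)
  seq <- random_sequence(23, seed = 2)
  prof <- shape_profile(seq, tb)
  oracle <- naive_shape_profile(seq, tb)
  expect_equal(prof$mgw, oracle$mgw)
  expect_equal(prof$prot, oracle$prot)
  expect_equal(prof$roll[-23], oracle$roll)
  expect_equal(prof$helt[-23], oracle$helt)
})

test_that("profile support is exactly where the pentamer window fits", {
  tb <- constant_shape_table(mgw = 4.2)
  p5 <- shape_profile("ACGTA", tb)
  expect_equal(which(!is.na(p5$mgw)), 3L) # single defined entry, center
  expect_equal(p5$mgw[3], 4.2)
  expect_true(all(is.na(p5$roll))) # length 5 has no defined step

  p7 <- shape_profile("ACGTACG", tb)
  expect_equal(which(!is.na(p7$mgw)), 3:5)
  expect_equal(which(!is.na(p7$roll)), 3:4)
  # constant table: every defined entry equals the constant
  expect_true(all(p7$mgw[3:5] == 4.2))

  expect_error(shape_profile("ACGT", tb), class = "tstv_error_length")
  expect_error(shape_profile("ACGTN", tb), class = "tstv_error_alphabet")
})

test_that("mutation shape effects are local, symmetric, and zero under a constant table", {
  tb <- gen_shape_table(4)
  const <- constant_shape_table()
  s <- random_sequence(61, seed = 8)
  s2 <- s
  old <- substr(s, 31, 31)
  substr(s2, 31, 31) <- setdiff(DNA_BASES, old)[1]

  e_const <- mutation_shape_effect(s, s2, const)
  expect_equal(unlist(e_const[c("d_mgw", "d_prot", "d_roll", "d_helt")]),
               c(d_mgw = 0, d_prot = 0, d_roll = 0, d_helt = 0))

  full <- mutation_shape_effect(s, s2, tb, method = "full")
  win <- mutation_shape_effect(s, s2, tb, method = "window")
  expect_equal(full, win)
  # symmetry under swapping the two sequences
  expect_equal(mutation_shape_effect(s2, s, tb), full)

  # locality: differences vanish outside the +/-2 bp window
  pa <- shape_profile(s, tb); pb <- shape_profile(s2, tb)
  d_mgw <- abs(pa$mgw - pb$mgw)
  expect_true(all(d_mgw[setdiff(which(!is.na(d_mgw)), 29:33)] == 0))

  expect_error(mutation_shape_effect(s, s, tb), class = "tstv_error_pairing")
  s3 <- s2; substr(s3, 5, 5) <- setdiff(DNA_BASES, substr(s, 5, 5))[1]
  expect_error(mutation_shape_effect(s, s3, tb), class = "tstv_error_pairing")
})

test_that("the quartet experiment yields 6 pairs (2 Ts : 4 Tv) per sequence", {
  tb <- gen_shape_table(5)
  eff <- run_shape_experiment(10, length = 51, table = tb, seed = 21)
  expect_equal(nrow(eff), 60L)
  expect_equal(sum(eff$klass == "TS"), 20L)
  expect_equal(sum(eff$klass == "TV"), 40L)
  # the TS pairs are exactly A-G and C-T
  ts_pairs <- unique(paste(eff$base_a, eff$base_b)[eff$klass == "TS"])
  expect_setequal(ts_pairs, c("A G", "C T"))

  # determinism
  expect_identical(eff, run_shape_experiment(10, length = 51, table = tb,
                                             seed = 21))
  expect_error(run_shape_experiment(5, length = 100, table = tb, seed = 1),
               class = "tstv_error_argument")
})

test_that("quartet deltas equal full-profile brute force", {
  tb <- gen_shape_table(17)
  n <- 20
  eff <- run_shape_experiment(n, length = 503, table = tb, seed = 31)
  seqs <- random_sequence(503, n = n, seed = 31)
  c0 <- 252L
  for (q in sample(n, 4)) {
    variants <- vapply(DNA_BASES, function(b) {
      v <- seqs[q]; substr(v, c0, c0) <- b; v
    }, character(1))
    pr <- lapply(variants, shape_profile, table = tb)
    for (k in which(eff$quartet_id == q)) {
      a <- pr[[eff$base_a[k]]]; b <- pr[[eff$base_b[k]]]
      expect_equal(eff$d_mgw[k], sum(abs(a$mgw - b$mgw), na.rm = TRUE))
      expect_equal(eff$d_roll[k], sum(abs(a$roll - b$roll), na.rm = TRUE))
    }
  }
})

test_that("class comparison absorbs quartet identity like explicit dummies", {
  tb <- gen_shape_table(6)
  eff <- run_shape_experiment(50, length = 51, table = tb, seed = 12)
  cmp <- compare_shape_effects(eff)
  # explicit dummy regression oracle
  for (p in c("mgw", "roll")) {
    fit <- lm(eff[[paste0("d_", p)]] ~ I(eff$klass == "TV") +
                factor(eff$quartet_id))
    sm <- summary(fit)$coefficients[2, ]
    row <- cmp$coefs[cmp$coefs$term == paste0("tv_", p), ]
    expect_equal(row$estimate, unname(sm[1]), tolerance = 1e-10)
    expect_equal(row$std.error, unname(sm[2]), tolerance = 1e-10)
    expect_equal(row$p.value, unname(sm[4]), tolerance = 1e-10)
  }
  expect_error(compare_shape_effects(dplyr::filter(eff, klass == "TV")),
               class = "tstv_error_degenerate_design")
})

test_that("planted Tv/Ts delta ratios are recovered", {
  # synthetic effects: TV deltas exactly 2x TS deltas
  withr::with_seed(77, {
    n_q <- 200
    base <- rexp(n_q * 6, rate = 1)
    eff <- tibble::tibble(
      quartet_id = rep(seq_len(n_q), each = 6),
      klass = rep(c("TS", "TS", "TV", "TV", "TV", "TV"), times = n_q),
      d_mgw = base * ifelse(rep(c("TS", "TS", "TV", "TV", "TV", "TV"),
                                times = n_q) == "TV", 2, 1)
    )
    eff$d_prot <- eff$d_mgw; eff$d_roll <- eff$d_mgw; eff$d_helt <- eff$d_mgw
    cmp <- compare_shape_effects(eff)
    expect_equal(cmp$summary$ratio_tv_ts[1], 2, tolerance = 0.15)
  })
})
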