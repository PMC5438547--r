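test_that("middle third uses floor arithmetic and nests properly", {
  expect_equal(middle_third(0, 300), tibble::tibble(start = 100, end = 200))
  expect_equal(middle_third(0, 10), tibble::tibble(start = 3, end = 6))
  expect_error(middle_third(5, 5), class = "tstv_error_argument")

  # nesting: the middle third of the middle third stays inside
  m1 <- middle_third(120, 571)
  m2 <- middle_third(m1$start, m1$end)
  expect_gte(m2$start, m1$start)
  expect_lte(m2$end, m1$end)
  # length within 1 bp of L/3
  expect_lte(abs((m1$end - m1$start) - (571 - 120) / 3), 1)
})

test_that("haplotypes group by amplicon with conservation of members", {
  fx <- hand_haplo_fixture()
  g <- group_by_amplicon(fx$haplotypes, fx$amplicons)
  expect_equal(nrow(g), 2L)
  expect_equal(sort(g$n_haplotypes), c(2L, 3L))
  expect_equal(sum(g$n_haplotypes), nrow(fx$haplotypes))

  empty <- group_by_amplicon(fx$haplotypes[0, ], fx$amplicons)
  expect_equal(nrow(empty), 0L)

  orphan <- dplyr::mutate(fx$haplotypes[1, ], amplicon_id = "NOPE")
  expect_error(group_by_amplicon(orphan, fx$amplicons),
               class = "tstv_error_reference")
})

test_that("reference choice is seeded, uniform, and total", {
  fx <- hand_haplo_fixture()
  r1 <- choose_reference(fx$haplotypes, seed = 4)
  expect_identical(r1, choose_reference(fx$haplotypes, seed = 4))
  expect_equal(nrow(r1), 2L)

  # singleton group: that haplotype is the reference
  single <- fx$haplotypes[4, ]
  expect_equal(choose_reference(single, seed = 1)$reference_id, "A2_H1")

  # uniformity over seeds on a 4-haplotype group
  hp <- tibble::tibble(haplotype_id = paste0("H", 1:4), amplicon_id = "A")
  picks <- vapply(1:2000, function(s) choose_reference(hp, s)$reference_id,
                  character(1))
  freqs <- table(picks) / 2000
  expect_equal(length(freqs), 4L)
  expect_true(all(abs(freqs - 0.25) < 0.03))
})

test_that("contrasts count Ts/Tv differences site by site", {
  fx <- hand_haplo_fixture()
  ct <- build_contrasts(fx$haplotypes, fx$alleles, fx$refs, dhs = fx$dhs)
  expect_equal(nrow(ct), 3L) # references excluded
  expect_false(any(c("A1_H1", "A2_H1") %in% ct$haplotype_id))

  h2 <- ct[ct$haplotype_id == "A1_H2", ]
  # hand count: A>G (Ts), C>T (Ts), A>T (Tv); effect 2.0 vs 1.0
  expect_equal(h2$n_ts, 2L)
  expect_equal(h2$n_tv, 1L)
  expect_equal(h2$delta_mag, 1.0)
  expect_true(h2$has_ts && h2$has_tv)

  h3 <- ct[ct$haplotype_id == "A1_H3", ]
  expect_equal(h3$n_ts, 0L)
  expect_equal(h3$n_tv, 1L)
  expect_equal(h3$delta_mag, abs(log2(1.5)))

  # site-by-site brute-force oracle for every contrast
  for (k in seq_len(nrow(ct))) {
    hid <- ct$haplotype_id[k]
    rid <- fx$refs$reference_id[fx$refs$amplicon_id == ct$amplicon_id[k]]
    mine <- fx$alleles[fx$alleles$haplotype_id == hid, ]
    ref <- fx$alleles[fx$alleles$haplotype_id == rid, ]
    n_ts <- 0; n_tv <- 0
    for (i in seq_len(nrow(mine))) {
      rb <- ref$base[ref$pos == mine$pos[i]]
      if (rb != mine$base[i]) {
        if (classify_substitution(rb, mine$base[i]) == "TS") {
          n_ts <- n_ts + 1
        } else {
          n_tv <- n_tv + 1
        }
      }
    }
    expect_equal(ct$n_ts[k], n_ts)
    expect_equal(ct$n_tv[k], n_tv)
  }
})

test_that("contrast magnitude and counts are symmetric in the reference choice", {
  fx <- hand_haplo_fixture()
  refs_a <- tibble::tibble(amplicon_id = "A1", reference_id = "A1_H1")
  refs_b <- tibble::tibble(amplicon_id = "A1", reference_id = "A1_H2")
  hp <- fx$haplotypes[fx$haplotypes$amplicon_id == "A1", ]
  ct_a <- build_contrasts(hp, fx$alleles, refs_a)
  ct_b <- build_contrasts(hp, fx$alleles, refs_b)
  a <- ct_a[ct_a$haplotype_id == "A1_H2", ]
  b <- ct_b[ct_b$haplotype_id == "A1_H1", ]
  expect_equal(a$delta_mag, b$delta_mag)
  expect_equal(a$n_ts, b$n_ts)
  expect_equal(a$n_tv, b$n_tv)
})

test_that("Hamming distance equals n_ts + n_tv on generated data", {
  cfg <- sim_config(seed = 23, n_amplicons = 10, haplotypes_per_amplicon = 5)
  d <- gen_haplotype_dataset(cfg)
  refs <- generative_refs(d)
  ct <- build_contrasts(d$haplotypes, d$alleles, refs, dhs = d$dhs)
  seqs <- setNames(d$sequences$seq, d$sequences$haplotype_id)
  ref_of <- setNames(refs$reference_id, refs$amplicon_id)
  for (k in seq_len(nrow(ct))) {
    a <- strsplit(seqs[[ct$haplotype_id[k]]], "")[[1]]
    b <- strsplit(seqs[[ref_of[[ct$amplicon_id[k]]]]], "")[[1]]
    expect_equal(ct$n_ts[k] + ct$n_tv[k], sum(a != b))
  }
  expect_true(all(ct$n_ts_mid <= ct$n_ts))
  expect_true(all(ct$n_tv_mid <= ct$n_tv))
})

test_that("mismatched site sets are rejected", {
  fx <- hand_haplo_fixture()
  broken <- fx$alleles[-2, ] # drop one allele of A1_H1
  expect_error(build_contrasts(fx$haplotypes, broken, fx$refs),
               class = "tstv_error_alignment")
})

test_that("alleles derived from sequences agree with planted alleles", {
  cfg <- sim_config(seed = 31, n_amplicons = 8, haplotypes_per_amplicon = 6)
  d <- gen_haplotype_dataset(cfg)
  al <- alleles_from_sequences(d$sequences, d$amplicons)
  # sequence-derived sites are the planted sites that are actually
  # polymorphic among the drawn haplotypes; alleles there must agree
  merged <- dplyr::inner_join(al, d$alleles,
                              by = c("haplotype_id", "pos"),
                              suffix = c("_seq", "_planted"))
  expect_equal(nrow(merged), nrow(al))
  expect_equal(merged$base_seq, merged$base_planted)
  # contrasts built from either allele source coincide
  refs <- generative_refs(d)
  ct_seq <- build_contrasts(d$haplotypes, al, refs)
  ct_pl <- build_contrasts(d$haplotypes, d$alleles, refs)
  expect_equal(ct_seq, ct_pl)
})

test_that("the group filter keeps exactly the amplicons with a significant haplotype", {
  fx <- hand_haplo_fixture()
  ct <- build_contrasts(fx$haplotypes, fx$alleles, fx$refs)
  kept <- filter_groups(ct, fx$haplotypes, alpha = 0.05)
  # A1 has p = 0.01 < 0.05 (the reference itself); A2 has min p = 0.5
  expect_setequal(unique(kept$amplicon_id), "A1")

  # independent filter oracle on a 50-group synthetic fixture
  cfg <- sim_config(seed = 41, n_amplicons = 50, haplotypes_per_amplicon = 4)
  d <- gen_haplotype_dataset(cfg, sig_fraction = 0.2)
  refs <- generative_refs(d)
  ctg <- build_contrasts(d$haplotypes, d$alleles, refs)
  keptg <- filter_groups(ctg, d$haplotypes)
  oracle <- unique(d$haplotypes$amplicon_id[
    d$haplotypes$amplicon_id %in%
      names(which(tapply(d$haplotypes$effect_p,
                         d$haplotypes$amplicon_id, min) < 0.05))
  ])
  expect_setequal(unique(keptg$amplicon_id), oracle)

  bad <- fx$haplotypes
  bad$effect_p[1] <- NA
  expect_error(filter_groups(ct, bad), class = "tstv_error_data")
})

test_that("OLS fits match a hand-written normal-equations oracle", {
  cfg <- sim_config(seed = 51, n_amplicons = 20, haplotypes_per_amplicon = 6)
  d <- gen_haplotype_dataset(cfg)
  refs <- generative_refs(d)
  ct <- build_contrasts(d$haplotypes, d$alleles, refs, dhs = d$dhs)
  fit <- fit_model(ct, "count")

  # independent route: normal equations with explicit dummy columns
  X <- cbind(1, ct$n_ts, ct$n_tv,
             stats::model.matrix(~ amplicon_id, data = ct)[, -1])
  beta <- solve(t(X) %*% X, t(X) %*% ct$delta_mag)
  resid <- ct$delta_mag - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(t(X) %*% X)) * sigma2)
  expect_equal(fit$coefs$estimate, unname(beta[2:3]), tolerance = 1e-8)
  expect_equal(fit$coefs$std.error, unname(se[2:3]), tolerance = 1e-8)

  # noiseless data with no amplicon offsets: exact recovery
  ct0 <- ct
  ct0$delta_mag <- 0.06 * ct0$n_ts + 0.12 * ct0$n_tv
  fit0 <- suppressWarnings(fit_model(ct0, "count")) # exact fit by design
  expect_equal(fit0$coefs$estimate, c(0.06, 0.12), tolerance = 1e-10)

  # rank-deficient design is reported, naming the term
  collinear <- ct
  collinear$n_tv <- collinear$n_ts
  expect_error(fit_model(collinear, "count"),
               class = "tstv_error_degenerate_design")
  expect_error(fit_model(ct[ct$amplicon_id == ct$amplicon_id[1], ], "count"),
               class = "tstv_error_degenerate_design")
})

test_that("presence and middle-third models run, jointly and separately", {
  cfg <- sim_config(seed = 61, n_amplicons = 30, haplotypes_per_amplicon = 6)
  d <- gen_haplotype_dataset(cfg)
  ct <- build_contrasts(d$haplotypes, d$alleles, generative_refs(d),
                        dhs = d$dhs)
  fp <- fit_model(ct, "presence")
  expect_equal(fp$coefs$term, c("has_ts", "has_tv"))
  fm <- fit_model(ct, "count_mid")
  expect_equal(fm$coefs$term, c("n_ts_mid", "n_tv_mid"))
  fs <- fit_model(ct, "count", joint = FALSE)
  expect_equal(nrow(fs$coefs), 2L)
  # broom-style accessors
  expect_s3_class(tidy(fp), "tbl_df")
  expect_equal(glance(fp)$nobs, nrow(ct))
})
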