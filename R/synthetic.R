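#' Simulation configuration
#'
#' Bundles the scale and planted-effect parameters shared by the
#' synthetic-data generators. The planted defaults are the effect sizes
#' the package's analyses are designed to detect: per-variant activity
#' effects `beta_ts = 0.06` and `beta_tv = 0.12` (|log2 fold change| per
#' additional substitution), transversion fractions 0.3933 among
#' allele-specific-binding variants vs 0.3416 among tested variants, a
#' 1.5x transversion scale multiplier for shape/saturation arms, and
#' residual noise (`noise_sd = 0.03` on the log2 activity scale) at the
#' scale of the standard errors those coefficient estimates carry.
#'
#' @param seed Integer seed.
#' @param scenario `"planted"` (effects at their defaults) or `"null"`
#'   (all planted effects switched off).
#' @param n_sequences,n_motifs,n_snps,n_amplicons,haplotypes_per_amplicon,n_elements,element_length
#'   Scale parameters per analysis arm.
#' @param beta_ts,beta_tv,tv_shape_multiplier,asb_tv_fraction,tested_tv_fraction,noise_sd
#'   Planted-effect parameters (ignored where a scenario overrides them).
#' @return A list of class `tstv_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       scenario = c("planted", "null"),
                       n_sequences = 1000L,
                       n_motifs = 50L,
                       n_snps = 50000L,
                       n_amplicons = 100L,
                       haplotypes_per_amplicon = 8L,
                       n_elements = 3L,
                       element_length = 200L,
                       beta_ts = 0.06,
                       beta_tv = 0.12,
                       tv_shape_multiplier = 1.5,
                       asb_tv_fraction = 0.3933,
                       tested_tv_fraction = 0.3416,
                       noise_sd = 0.03) {
  scenario <- match.arg(scenario)
  counts <- c(n_sequences = n_sequences, n_motifs = n_motifs,
              n_snps = n_snps, n_amplicons = n_amplicons,
              haplotypes_per_amplicon = haplotypes_per_amplicon,
              n_elements = n_elements, element_length = element_length)
  if (any(counts < 1)) {
    abort("all scale parameters must be >= 1", class = "tstv_error_argument")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0", class = "tstv_error_argument")
  if (asb_tv_fraction < 0 || asb_tv_fraction > 1 ||
      tested_tv_fraction < 0 || tested_tv_fraction > 1) {
    abort("fractions must lie in [0, 1]", class = "tstv_error_argument")
  }
  if (scenario == "null") {
    beta_ts <- 0; beta_tv <- 0
    tv_shape_multiplier <- 1
    asb_tv_fraction <- tested_tv_fraction
  }
  structure(
    list(seed = as.integer(seed), scenario = scenario,
         n_sequences = n_sequences, n_motifs = n_motifs, n_snps = n_snps,
         n_amplicons = n_amplicons,
         haplotypes_per_amplicon = haplotypes_per_amplicon,
         n_elements = n_elements, element_length = element_length,
         beta_ts = beta_ts, beta_tv = beta_tv,
         tv_shape_multiplier = tv_shape_multiplier,
         asb_tv_fraction = asb_tv_fraction,
         tested_tv_fraction = tested_tv_fraction,
         noise_sd = noise_sd),
    class = "tstv_sim_config"
  )
}

#' Generate a synthetic pentamer shape table
#'
#' Draws all 1024 pentamer entries uniformly within physically plausible
#' ranges (MGW 2.8-6.2 Angstrom; ProT -18-0 deg; Roll -8-10 deg; HelT
#' 30-40 deg). The table exercises every code path of the shape arm but
#' carries no real structural signal; for directional claims about real
#' DNA, supply an experimentally derived pentamer table instead.
#'
#' @param seed Integer seed.
#' @return A validated shape-table tibble (1024 rows).
#' @export
gen_shape_table <- function(seed) {
  withr::with_seed(seed, {
    p <- all_pentamers()
    tibble(
      pentamer = p,
      mgw = runif(1024, 2.8, 6.2),
      prot = runif(1024, -18, 0),
      roll = runif(1024, -8, 10),
      helt = runif(1024, 30, 40)
    )
  })
}

#' Generate a synthetic motif library
#'
#' Count columns are drawn from a Dirichlet-multinomial: per position the
#' base probabilities come from a symmetric Dirichlet with the given
#' `concentration` (small values give sharp, high-information-content
#' columns; large values give near-uniform, low-IC columns), and
#' `n_sites` observed sites are multinomially distributed over the bases.
#'
#' @param n_motifs Number of motifs.
#' @param length_range Integer range of motif lengths, inclusive.
#' @param concentration Positive Dirichlet concentration parameter.
#' @param n_sites Sites (column total) per position.
#' @param seed Integer seed.
#' @return A tidy PFM tibble (see [read_jaspar()]).
#' @export
gen_motif_library <- function(n_motifs, length_range = c(6L, 12L),
                              concentration = 0.5, n_sites = 100L, seed = 1L) {
  if (concentration <= 0) {
    abort("`concentration` must be > 0", class = "tstv_error_argument")
  }
  withr::with_seed(seed, {
    bind_rows(lapply(seq_len(n_motifs), function(k) {
      L <- sample(seq(length_range[1], length_range[2]), 1)
      counts <- vapply(seq_len(L), function(i) {
        g <- rgamma(4, shape = concentration)
        if (sum(g) == 0) g <- rep(1, 4)
        rmultinom(1, n_sites, g / sum(g))[, 1]
      }, numeric(4))
      tibble(
        motif_id = sprintf("SYN%04d", k),
        name = sprintf("synthetic_%d", k),
        position = rep(seq_len(L), each = 4),
        base = rep(DNA_BASES, times = L),
        count = as.vector(counts)
      )
    }))
  })
}

# draw ref/alt pairs for n SNVs with the given probability of TV class
draw_substitutions <- function(n, tv_prob) {
  is_tv <- runif(n) < tv_prob
  ref <- sample(DNA_BASES, n, replace = TRUE)
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  # each base has two transversion partners; pick one uniformly
  tv_partner1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv_partner2 <- c(A = "T", G = "T", C = "G", T = "G")
  pick2 <- runif(n) < 0.5
  alt <- ifelse(is_tv,
                ifelse(pick2, tv_partner2[ref], tv_partner1[ref]),
                ts_partner[ref])
  tibble(ref = ref, alt = unname(alt),
         klass = if_else(is_tv, "TV", "TS"))
}

#' Generate a synthetic allele-specific binding dataset
#'
#' Tested SNPs carry a transversion with probability
#' `tested_tv_fraction`; a subset of `n_asb` of them is flagged ASB,
#' drawn so that the ASB transversion fraction is `asb_tv_fraction`
#' (class-stratified resampling). SNPs are assigned to groups (TFs or
#' cell lines) round-robin, and a configurable fraction of variants is
#' duplicated into a second group to exercise redundant-variant
#' collapsing.
#'
#' @param n_tested Number of tested SNPs.
#' @param tested_tv_fraction Tv fraction among tested SNPs.
#' @param n_asb Number of ASB SNPs (`<= n_tested`).
#' @param asb_tv_fraction Tv fraction among ASB SNPs.
#' @param n_groups Number of TF/cell-line groups.
#' @param dup_rate Fraction of records duplicated into another group.
#' @param seed Integer seed.
#' @return Tibble of SNP records: `chrom`, `pos`, `ref`, `alt`, `klass`,
#'   `group`, `is_asb`.
#' @export
gen_asb_dataset <- function(n_tested, tested_tv_fraction, n_asb,
                            asb_tv_fraction, n_groups = 6L,
                            dup_rate = 0, seed = 1L) {
  if (n_asb > n_tested) {
    abort("`n_asb` must be <= `n_tested`", class = "tstv_error_argument")
  }
  withr::with_seed(seed, {
    subs <- draw_substitutions(n_tested, tested_tv_fraction)
    snps <- bind_cols(
      tibble(chrom = "chr1",
             pos = sort(sample.int(2e8, n_tested))),
      subs
    )
    snps$group <- paste0("G", rep_len(seq_len(n_groups), n_tested))
    # class-stratified ASB draw so the planted ASB Tv fraction holds
    n_tv_asb <- rbinom(1, n_asb, asb_tv_fraction)
    tv_idx <- which(snps$klass == "TV")
    ts_idx <- which(snps$klass == "TS")
    n_tv_asb <- min(n_tv_asb, length(tv_idx))
    n_ts_asb <- min(n_asb - n_tv_asb, length(ts_idx))
    asb_idx <- c(sample(tv_idx, n_tv_asb), sample(ts_idx, n_ts_asb))
    snps$is_asb <- seq_len(n_tested) %in% asb_idx
    if (dup_rate > 0) {
      n_dup <- floor(dup_rate * n_tested)
      if (n_dup > 0) {
        dup <- snps[sample.int(n_tested, n_dup), ]
        gi <- match(dup$group, paste0("G", seq_len(n_groups)))
        dup$group <- paste0("G", gi %% n_groups + 1L)
        snps <- bind_rows(snps, dup)
      }
    }
    arrange(snps, .data$chrom, .data$pos, .data$group)
  })
}

#' Generate a synthetic population-scale haplotype reporter dataset
#'
#' Emulates the inputs of the haplotype regression arm. Per amplicon, a
#' random reference sequence is drawn; segregating sites (Poisson count)
#' receive an alternative allele drawn uniformly from the three other
#' bases (1:2 Ts:Tv on average; `ts_bias` can skew this toward the ~2:1
#' Ts:Tv ratio of natural variation). The first haplotype of each
#' amplicon is the generative reference (`reference = TRUE`); every other
#' haplotype carries the alternative allele at each site with probability
#' `maf`, and its log2 activity is
#' `log2(ref effect) + beta_ts * n_ts + beta_tv * n_tv + N(0, noise_sd)`,
#' with per-amplicon baseline offsets. A configurable fraction of
#' haplotypes receives an effect p-value below 0.05 so the group filter
#' has work to do.
#'
#' @param config A [sim_config()].
#' @param amplicon_length Amplicon width in bp.
#' @param mean_sites Poisson mean of segregating sites per amplicon.
#' @param maf Probability a haplotype carries the alternative allele at a
#'   site.
#' @param amplicon_sd SD of the per-amplicon baseline log2 activity.
#' @param sig_fraction Fraction of haplotypes given `effect_p < 0.05`.
#' @param ts_bias Probability that a site's alternative allele is the
#'   transition partner (1/3 = uniform draw over the three alternatives).
#' @return A list: `haplotypes` (with `reference` flag), `alleles`,
#'   `amplicons`, `dhs`, `variants`, `sequences`, plus the `config`.
#' @export
gen_haplotype_dataset <- function(config,
                                  amplicon_length = 425L,
                                  mean_sites = 5,
                                  maf = 0.3,
                                  amplicon_sd = 0.5,
                                  sig_fraction = 0.5,
                                  ts_bias = 1 / 3) {
  stopifnot(inherits(config, "tstv_sim_config"))
  withr::with_seed(config$seed, {
    A <- config$n_amplicons
    H <- config$haplotypes_per_amplicon
    parts <- lapply(seq_len(A), function(a) {
      amp_id <- sprintf("AMP%03d", a)
      start <- 1e6 + (a - 1) * (amplicon_length + 200)
      end <- start + amplicon_length
      dhs_pad <- sample(30:60, 1)
      ref_seq <- random_sequence(amplicon_length)
      # haplotypes are unique sequences, so at least ceil(log2(H)) sites
      # are needed to accommodate H distinct allele vectors; cap keeps
      # the distinct-vector enumeration below small
      S <- max(rpois(1, mean_sites), ceiling(log2(H)))
      S <- min(S, 14L, amplicon_length)
      site_pos <- sort(sample.int(amplicon_length, S))
      site_ref <- if (S > 0) {
        vapply(site_pos, function(p) substr(ref_seq, p, p), character(1))
      } else character(0)
      ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
      tv_partner <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))
      site_alt <- if (S > 0) {
        vapply(site_ref, function(b) {
          if (runif(1) < ts_bias) ts_partner[[b]] else sample(tv_partner[[b]], 1)
        }, character(1))
      } else character(0)
      site_klass <- if (S > 0) classify_substitution(site_ref, site_alt) else character(0)
      hap_ids <- sprintf("%s_H%02d", amp_id, seq_len(H))
      # allele matrix H x S: TRUE = alternative allele. The reference is
      # the all-ref vector; the other haplotypes are distinct non-zero
      # carrier vectors drawn with weight maf^k (1-maf)^(S-k), mirroring
      # that assayed haplotypes are unique sequences.
      alt_carrier <- matrix(FALSE, H, S)
      if (H > 1) {
        pool <- seq_len(2^S - 1) # non-zero vectors, coded as integers
        bits <- outer(pool, 2^(0:(S - 1)), bitwAnd) > 0
        popcount <- rowSums(bits)
        w <- maf^popcount * (1 - maf)^(S - popcount)
        chosen <- sample(pool, H - 1, prob = w)
        alt_carrier[-1, ] <- bits[chosen, , drop = FALSE]
      }
      n_ts <- if (S > 0) {
        as.vector(alt_carrier[, seq_len(S), drop = FALSE] %*% (site_klass == "TS"))
      } else rep(0, H)
      n_tv <- if (S > 0) {
        as.vector(alt_carrier[, seq_len(S), drop = FALSE] %*% (site_klass == "TV"))
      } else rep(0, H)
      base_log2 <- rnorm(1, 0, amplicon_sd)
      log2_eff <- base_log2 + config$beta_ts * n_ts + config$beta_tv * n_tv +
        c(0, rnorm(H - 1, 0, config$noise_sd))
      sig <- runif(H) < sig_fraction
      effect_p <- ifelse(sig, runif(H, 0, 0.049), runif(H, 0.051, 1))
      haplotypes <- tibble::new_tibble(list(
        haplotype_id = hap_ids, amplicon_id = rep(amp_id, H),
        effect_size = 2^log2_eff, effect_p = effect_p,
        reference = seq_len(H) == 1
      ), nrow = H)
      alleles <- if (S > 0) {
        tibble::new_tibble(list(
          haplotype_id = rep(hap_ids, times = S),
          pos = rep(start + site_pos, each = H),
          # H x S matrix read column-major: site-major with haplotype
          # varying fastest, matching the id/pos ordering above
          base = as.vector(ifelse(alt_carrier[, seq_len(S), drop = FALSE],
                                  matrix(site_alt, H, S, byrow = TRUE),
                                  matrix(site_ref, H, S, byrow = TRUE)))
        ), nrow = H * S)
      } else {
        tibble(haplotype_id = character(), pos = numeric(), base = character())
      }
      sequences <- tibble::new_tibble(list(
        haplotype_id = hap_ids, amplicon_id = rep(amp_id, H),
        seq = vapply(seq_len(H), function(i) {
          s <- ref_seq
          if (S > 0) for (k in seq_len(S)) {
            if (alt_carrier[i, k]) substr(s, site_pos[k], site_pos[k]) <- site_alt[k]
          }
          s
        }, character(1))
      ), nrow = H)
      list(
        haplotypes = haplotypes, alleles = alleles, sequences = sequences,
        amplicons = tibble::new_tibble(list(
          amplicon_id = amp_id, chrom = "chr3",
          start = start, end = end), nrow = 1L),
        dhs = tibble::new_tibble(list(
          amplicon_id = amp_id, chrom = "chr3",
          start = start + dhs_pad, end = end - dhs_pad), nrow = 1L),
        variants = if (S > 0) {
          tibble::new_tibble(list(
            chrom = rep("chr3", S), pos = start + site_pos,
            ref = site_ref, alt = unname(site_alt)), nrow = S)
        } else {
          tibble(chrom = character(), pos = numeric(),
                 ref = character(), alt = character())
        }
      )
    })
    pick <- function(nm) bind_rows(lapply(parts, `[[`, nm))
    list(
      haplotypes = pick("haplotypes"), alleles = pick("alleles"),
      amplicons = pick("amplicons"), dhs = pick("dhs"),
      variants = pick("variants"), sequences = pick("sequences"),
      config = config
    )
  })
}

#' Write a synthetic haplotype dataset to standard file formats
#'
#' @param dataset Output of [gen_haplotype_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisible named vector of the file paths written (haplotype
#'   effects TSV, amplicon BED, DHS BED, variants VCF, haplotype
#'   sequences FASTA).
#' @export
write_haplotype_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    effects = file.path(dir, "haplotype_effects.tsv"),
    amplicons = file.path(dir, "amplicons.bed"),
    dhs = file.path(dir, "dhs.bed"),
    variants = file.path(dir, "variants.vcf"),
    sequences = file.path(dir, "haplotypes.fasta")
  )
  readr::write_tsv(
    select(dataset$haplotypes, "haplotype_id", "amplicon_id",
           "effect_size", "effect_p", "reference"),
    paths["effects"]
  )
  write_bed(mutate(dataset$amplicons, name = .data$amplicon_id),
            paths["amplicons"])
  write_bed(mutate(dataset$dhs, name = .data$amplicon_id), paths["dhs"])
  write_snv_vcf(dataset$variants, paths["variants"])
  write_fasta(
    tibble(name = dataset$sequences$haplotype_id,
           seq = dataset$sequences$seq),
    paths["sequences"]
  )
  invisible(paths)
}

#' Generate a synthetic saturation-mutagenesis dataset
#'
#' A complete saturation design: every position of every element carries
#' all three alternative bases (1 transition + 2 transversions).
#' True |log2 fold change| magnitudes are half-normal with scale
#' `base_scale`, multiplied by `tv_multiplier` for transversions and
#' optionally boosted toward the element centre
#' (`scale * (1 + center_weight * (1 - 2 d))` with `d` the scaled
#' distance from the centre). Signs are random; replicate fold changes
#' add lognormal noise.
#'
#' @param n_elements,element_length Design size.
#' @param tv_multiplier Transversion scale multiplier (1 = null).
#' @param center_weight Centre boost (0 = uniform across the element).
#' @param replicates Number of replicate columns.
#' @param base_scale Half-normal scale of transition |log2FC|.
#' @param noise_sd SD (log scale) of the lognormal replicate noise.
#' @param seed Integer seed.
#' @return A saturation-mutagenesis tibble (see [read_satmut()]).
#' @export
gen_satmut_dataset <- function(n_elements = 3L, element_length = 200L,
                               tv_multiplier = 1.5, center_weight = 0,
                               replicates = 2L, base_scale = 0.4,
                               noise_sd = 0.1, seed = 1L) {
  if (replicates < 1) {
    abort("`replicates` must be >= 1", class = "tstv_error_argument")
  }
  withr::with_seed(seed, {
    bind_rows(lapply(seq_len(n_elements), function(e) {
      L <- element_length
      ref_seq <- strsplit(random_sequence(L), "", fixed = TRUE)[[1]]
      grid <- tidyr::expand_grid(position = 0:(L - 1), alt = DNA_BASES)
      grid$ref <- ref_seq[grid$position + 1]
      grid <- filter(grid, .data$ref != .data$alt)
      grid$klass <- classify_substitution(grid$ref, grid$alt)
      d <- abs(grid$position - (L - 1) / 2) / ((L - 1) / 2) # 0 centre, 1 edge
      scale <- base_scale * (1 + center_weight * (1 - d)) *
        if_else(grid$klass == "TV", tv_multiplier, 1)
      mag <- abs(rnorm(nrow(grid), 0, scale))
      sgn <- sample(c(-1, 1), nrow(grid), replace = TRUE)
      true_fc <- 2^(sgn * mag)
      reps <- vapply(seq_len(replicates), function(r) {
        true_fc * exp(rnorm(nrow(grid), 0, noise_sd))
      }, numeric(nrow(grid)))
      colnames(reps) <- paste0("rep", seq_len(replicates))
      bind_cols(
        tibble(element = sprintf("ENH%d", e)),
        select(grid, "position", "ref", "alt", "klass"),
        as_tibble(reps)
      )
    }))
  })
}
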