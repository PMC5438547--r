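#' Middle third of a genomic interval
#'
#' Intervals are 0-based half-open (BED convention). The middle third of
#' `[start, end)` with `L = end - start` is
#' `[start + floor(L/3), start + floor(2L/3))`; it is contained in the
#' input and its length is within 1 bp of `L/3`.
#'
#' @param start,end Integer vectors (recycled) with `end > start`.
#' @return Tibble with columns `start`, `end`.
#' @export
middle_third <- function(start, end) {
  if (any(end <= start)) {
    abort("`end` must exceed `start`", class = "tstv_error_argument")
  }
  L <- end - start
  lo <- start + floor(L / 3)
  hi <- start + floor(2 * L / 3)
  tibble(start = lo, end = hi)
}

# 1-based variant position inside a 0-based half-open interval?
pos_in_interval <- function(pos, start, end) {
  (pos - 1) >= start & (pos - 1) < end
}

#' Group haplotypes by amplicon
#'
#' Haplotypes measured in a population-scale reporter assay are only
#' directly comparable within the amplicon (identical start/stop
#' coordinates) they were captured from. Returns one row per amplicon with
#' its member haplotypes nested.
#'
#' @param haplotypes Tibble with `haplotype_id`, `amplicon_id`,
#'   `effect_size`, `effect_p`.
#' @param amplicons Tibble of amplicon intervals: `amplicon_id`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @return Nested tibble: `amplicon_id`, `chrom`, `start`, `end`,
#'   `n_haplotypes`, `haplotypes` (list column).
#' @export
group_by_amplicon <- function(haplotypes, amplicons) {
  orphans <- setdiff(haplotypes$amplicon_id, amplicons$amplicon_id)
  if (length(orphans) > 0) {
    abort(paste0("haplotypes reference unknown amplicon(s): ",
                 paste(orphans, collapse = ", ")),
          class = "tstv_error_reference")
  }
  if (nrow(haplotypes) == 0) {
    return(tibble(amplicon_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  n_haplotypes = integer(), haplotypes = list()))
  }
  nested <- haplotypes |>
    tidyr::nest(haplotypes = -"amplicon_id") |>
    mutate(n_haplotypes = purrr::map_int(.data$haplotypes, nrow))
  amplicons |>
    select("amplicon_id", "chrom", "start", "end") |>
    inner_join(nested, by = "amplicon_id") |>
    relocate("haplotypes", .after = dplyr::last_col())
}

#' Choose a random reference haplotype per amplicon
#'
#' One haplotype per amplicon is designated the reference against which
#' all other members are contrasted. The draw is uniform and seeded;
#' amplicons are processed in sorted order so the result does not depend
#' on row order.
#'
#' @param haplotypes Tibble with `haplotype_id`, `amplicon_id`.
#' @param seed Integer seed.
#' @return Tibble: `amplicon_id`, `reference_id`.
#' @export
choose_reference <- function(haplotypes, seed) {
  if (nrow(haplotypes) == 0) {
    abort("no haplotypes to choose a reference from",
          class = "tstv_error_argument")
  }
  ids <- haplotypes |>
    distinct(.data$amplicon_id, .data$haplotype_id) |>
    arrange(.data$amplicon_id, .data$haplotype_id)
  withr::with_seed(seed, {
    ids |>
      group_by(.data$amplicon_id) |>
      summarise(reference_id = sample(.data$haplotype_id, 1L),
                .groups = "drop")
  })
}

#' Build haplotype-vs-reference contrasts
#'
#' For every non-reference haplotype of each amplicon, compares its
#' alleles at the amplicon's segregating sites to the reference
#' haplotype's alleles, classifies each differing site as a transition or
#' transversion, and records the magnitude of the activity change
#' `|log2(effect) - log2(effect_ref)|`. If a DHS interval table is given,
#' the differing sites falling inside the middle third of the DHS are
#' counted separately (`n_ts_mid`, `n_tv_mid`).
#'
#' @param haplotypes Tibble: `haplotype_id`, `amplicon_id`, `effect_size`,
#'   `effect_p`.
#' @param alleles Tibble of alleles at segregating sites: `haplotype_id`,
#'   `pos` (1-based genomic), `base`. Haplotypes with no segregating sites
#'   may be absent. All haplotypes of an amplicon must cover the same
#'   site set.
#' @param references Tibble `amplicon_id`, `reference_id` (from
#'   [choose_reference()] or supplied directly).
#' @param dhs Optional tibble `amplicon_id`, `start`, `end` (0-based
#'   half-open DHS interval).
#' @return Tibble with one row per non-reference haplotype:
#'   `haplotype_id`, `amplicon_id`, `delta_mag`, `n_ts`, `n_tv`,
#'   `has_ts`, `has_tv`, `n_ts_mid`, `n_tv_mid`.
#' @export
build_contrasts <- function(haplotypes, alleles, references, dhs = NULL) {
  hap <- left_join(haplotypes,
                   rename(references, ref_id = "reference_id"),
                   by = "amplicon_id")
  if (any(is.na(hap$ref_id))) {
    abort("missing reference for some amplicon(s)",
          class = "tstv_error_reference")
  }
  mid <- if (!is.null(dhs)) {
    bind_cols(select(dhs, "amplicon_id"),
              middle_third(dhs$start, dhs$end))
  } else {
    NULL
  }
  amp_of_hap <- setNames(hap$amplicon_id, hap$haplotype_id)
  al_amp <- amp_of_hap[alleles$haplotype_id]
  al_split <- split(
    alleles[!is.na(al_amp), c("haplotype_id", "pos", "base")],
    al_amp[!is.na(al_amp)]
  )
  out <- lapply(split(hap, hap$amplicon_id), function(h) {
    amp <- h$amplicon_id[1]
    ref_id <- h$ref_id[1]
    if (!ref_id %in% h$haplotype_id) {
      abort(paste0("reference ", ref_id, " is not a member of amplicon ", amp),
            class = "tstv_error_reference")
    }
    al <- al_split[[amp]]
    if (is.null(al)) al <- tibble(haplotype_id = character(),
                                  pos = numeric(), base = character())
    sites <- sort(unique(al$pos))
    # every member must carry an allele at every segregating site
    cover <- table(al$haplotype_id)
    if (length(sites) > 0 &&
        (!setequal(names(cover), h$haplotype_id) ||
         any(cover != length(sites)))) {
      abort(paste0("amplicon ", amp,
                   ": haplotypes do not share the same site set"),
            class = "tstv_error_alignment")
    }
    ref_effect <- h$effect_size[h$haplotype_id == ref_id]
    others <- h$haplotype_id != ref_id
    if (!any(others)) return(NULL)
    nh <- nrow(h)
    # sites x haplotypes base matrix
    M <- matrix(NA_character_, length(sites), nh)
    if (length(sites) > 0) {
      M[cbind(match(al$pos, sites), match(al$haplotype_id, h$haplotype_id))] <-
        al$base
    }
    ref_col <- match(ref_id, h$haplotype_id)
    D <- M != M[, ref_col] # TRUE where a haplotype differs from reference
    is_ts_site <- matrix(FALSE, length(sites), nh)
    idx <- which(D, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      is_ts_site[idx] <- classify_substitution(
        M[idx[, 1], ref_col], M[idx]
      ) == "TS"
    }
    mid_site <- if (!is.null(mid) && amp %in% mid$amplicon_id &&
                    length(sites) > 0) {
      m <- mid[mid$amplicon_id == amp, ]
      pos_in_interval(sites, m$start, m$end)
    } else {
      rep(FALSE, length(sites))
    }
    all_ts <- colSums(D & is_ts_site)[others]
    all_tv <- colSums(D & !is_ts_site)[others]
    all_ts_mid <- colSums(D & is_ts_site & mid_site)[others]
    all_tv_mid <- colSums(D & !is_ts_site & mid_site)[others]
    tibble::new_tibble(list(
      haplotype_id = h$haplotype_id[others],
      amplicon_id = rep(amp, sum(others)),
      delta_mag = abs(log2(h$effect_size[others]) - log2(ref_effect)),
      n_ts = all_ts, n_tv = all_tv,
      has_ts = all_ts > 0, has_tv = all_tv > 0,
      n_ts_mid = all_ts_mid, n_tv_mid = all_tv_mid
    ), nrow = sum(others))
  })
  bind_rows(out)
}

#' Derive segregating-site alleles from aligned haplotype sequences
#'
#' Column-wise comparison of the equal-length haplotype sequences of each
#' amplicon; columns where members disagree become segregating sites with
#' 1-based genomic position `amplicon start + column`.
#'
#' @param sequences Tibble: `haplotype_id`, `amplicon_id`, `seq`.
#' @param amplicons Tibble: `amplicon_id`, `start` (0-based).
#' @return Alleles tibble (`haplotype_id`, `pos`, `base`) usable with
#'   [build_contrasts()].
#' @export
alleles_from_sequences <- function(sequences, amplicons) {
  starts <- setNames(amplicons$start, amplicons$amplicon_id)
  out <- lapply(split(sequences, sequences$amplicon_id), function(s) {
    if (length(unique(nchar(s$seq))) != 1) {
      abort(paste0("amplicon ", s$amplicon_id[1],
                   ": haplotype sequences differ in length"),
            class = "tstv_error_alignment")
    }
    m <- do.call(rbind, strsplit(toupper(s$seq), "", fixed = TRUE))
    seg <- which(apply(m, 2, function(col) length(unique(col)) > 1))
    if (length(seg) == 0) return(NULL)
    tibble(
      haplotype_id = rep(s$haplotype_id, times = length(seg)),
      pos = rep(starts[s$amplicon_id[1]] + seg, each = nrow(s)),
      base = as.vector(m[, seg])
    )
  })
  arrange(bind_rows(out), .data$haplotype_id, .data$pos)
}

#' Filter amplicon groups by effect-size significance
#'
#' An amplicon group is retained only if at least one of its haplotypes
#' (reference included) has an activity effect p-value below `alpha`.
#'
#' @param contrasts Contrast tibble from [build_contrasts()].
#' @param haplotypes Haplotype tibble carrying `effect_p`.
#' @param alpha Significance cutoff (default 0.05).
#' @return The contrasts restricted to retained amplicons.
#' @export
filter_groups <- function(contrasts, haplotypes, alpha = 0.05) {
  if (any(is.na(haplotypes$effect_p))) {
    abort("missing effect p-values", class = "tstv_error_data")
  }
  keep <- haplotypes |>
    group_by(.data$amplicon_id) |>
    summarise(min_p = min(.data$effect_p), .groups = "drop") |>
    filter(.data$min_p < alpha) |>
    pull(.data$amplicon_id)
  filter(contrasts, .data$amplicon_id %in% keep)
}

#' Regress activity-change magnitude on Ts/Tv content
#'
#' Ordinary least squares of `delta_mag` on the substitution content of
#' each haplotype-vs-reference contrast, with the amplicon as a
#' categorical covariate:
#' * `presence`: indicators `has_ts`, `has_tv`;
#' * `count`: counts `n_ts`, `n_tv`;
#' * `count_mid`: counts restricted to the DHS middle third
#'   (`n_ts_mid`, `n_tv_mid`).
#'
#' @param contrasts Contrast tibble from [build_contrasts()] (after any
#'   [filter_groups()] step).
#' @param model `"presence"`, `"count"`, or `"count_mid"`.
#' @param joint Fit both class terms in one regression (default); if
#'   `FALSE`, each class term is fitted in its own regression (still with
#'   the amplicon covariate) and the two coefficient rows are combined.
#' @return A `tstv_fit` whose coefficient table holds the Ts and Tv terms
#'   (amplicon coefficients are absorbed and not reported).
#' @export
fit_model <- function(contrasts, model = c("presence", "count", "count_mid"),
                      joint = TRUE) {
  model <- match.arg(model)
  terms <- switch(model,
    presence = c("has_ts", "has_tv"),
    count = c("n_ts", "n_tv"),
    count_mid = c("n_ts_mid", "n_tv_mid")
  )
  n_amp <- dplyr::n_distinct(contrasts$amplicon_id)
  if (n_amp < 2) {
    abort("need contrasts from at least 2 amplicons",
          class = "tstv_error_degenerate_design")
  }
  dat <- mutate(contrasts,
                across(dplyr::all_of(terms), as.numeric),
                .amplicon = factor(.data$amplicon_id))
  fit_one <- function(tt) {
    f <- stats::as.formula(paste("delta_mag ~", paste(tt, collapse = " + "),
                                 "+ .amplicon"))
    fit <- lm(f, data = dat)
    if (any(is.na(coef(fit)[tt]))) {
      bad <- tt[is.na(coef(fit)[tt])]
      abort(paste0("rank-deficient design; inestimable term(s): ",
                   paste(bad, collapse = ", ")),
            class = "tstv_error_degenerate_design")
    }
    lm_coef_tbl(fit, keep = tt)
  }
  coefs <- if (joint) fit_one(terms) else bind_rows(lapply(terms, fit_one))
  new_tstv_fit(
    coefs,
    model_label = paste0("delta_mag ~ ", paste(terms, collapse = " + "),
                         " + amplicon [", model,
                         if (!joint) ", separate fits" else "", "]"),
    n_obs = nrow(dat),
    extra = list(model = model, n_amplicons = n_amp, joint = joint)
  )
}
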