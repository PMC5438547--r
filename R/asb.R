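#' Read an allele-specific binding call table
#'
#' Neutral TSV interface for published allele-specific binding (ASB)
#' calls: one row per tested SNP per TF/cell-line group, with a flag for
#' SNPs showing significant allele-specific binding. Expected columns:
#' `chrom`, `pos` (1-based), `ref`, `alt`, `group` (TF name or cell-line
#' label), `is_asb` (logical or 0/1).
#'
#' @param path Path to the TSV file.
#' @return A tibble with the columns above plus `klass` (`"TS"`/`"TV"`).
#' @export
read_asb_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("chrom", "pos", "ref", "alt", "group", "is_asb")
  if (!all(need %in% names(tbl))) {
    abort(paste0("ASB table needs columns: ", paste(need, collapse = ", ")),
          class = "tstv_error_table_format")
  }
  tbl$is_asb <- as.logical(tbl$is_asb)
  tbl$klass <- classify_substitution(tbl$ref, tbl$alt)
  as_tibble(tbl)
}

#' Collapse SNPs listed redundantly across groups
#'
#' Variants reported for several TFs or cell lines are collapsed to one
#' record per distinct `(chrom, pos, ref, alt)` key; a variant flagged ASB
#' in any group stays ASB. Output is deterministically sorted by chrom,
#' pos, ref, alt. Collapsing is idempotent.
#'
#' @param records Tibble of SNP records (`chrom`, `pos`, `ref`, `alt`,
#'   `klass`, `is_asb`; `group` optional and dropped).
#' @return Collapsed tibble, one row per distinct variant.
#' @export
collapse_redundant <- function(records) {
  if (nrow(records) == 0) {
    return(as_tibble(records)[0, setdiff(names(records), "group"), drop = FALSE])
  }
  key <- paste(records$chrom, records$pos, records$ref, records$alt)
  if (!anyDuplicated(key)) { # already unique: nothing to merge
    out <- select(as_tibble(records), "chrom", "pos", "ref", "alt",
                  "klass", "is_asb")
    return(arrange(out, .data$chrom, .data$pos, .data$ref, .data$alt))
  }
  chk <- records |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(n_klass = dplyr::n_distinct(.data$klass), .groups = "drop")
  if (any(chk$n_klass > 1)) {
    abort("conflicting Ts/Tv class for the same variant key",
          class = "tstv_error_data_integrity")
  }
  records |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(klass = first(.data$klass), is_asb = any(.data$is_asb),
              .groups = "drop") |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
}

#' Transversion fraction of a variant set
#'
#' @param records Tibble with a `klass` column of `"TS"`/`"TV"`.
#' @return Proportion of records that are transversions.
#' @export
tv_fraction <- function(records) {
  if (nrow(records) == 0) {
    abort("cannot take the Tv fraction of an empty variant set",
          class = "tstv_error_argument")
  }
  mean(records$klass == "TV")
}

#' Two-proportion Z-test (pooled variance)
#'
#' Compares two proportions by approximating the binomial with a normal:
#' pooled `p^ = (p1 n1 + p0 n0) / (n1 + n0)`,
#' `se = sqrt(p^ (1 - p^) (1/n1 + 1/n0))`, `z = (p1 - p0)/se`, two-tailed
#' `p = 2 Phi(-|z|)`.
#'
#' @param p1,n1 Proportion and sample size of the focal set (e.g. Tv
#'   fraction among ASB variants).
#' @param p0,n0 Proportion and sample size of the comparison set (all
#'   tested variants).
#' @return One-row tibble of class `tstv_enrichment`: `p1`, `n1`, `p0`,
#'   `n0`, `estimate` (p1 - p0), `se`, `z`, `p.value`.
#' @export
two_tailed_z_test <- function(p1, n1, p0, n0) {
  if (n1 < 1 || n0 < 1) {
    abort("sample sizes must be >= 1", class = "tstv_error_argument")
  }
  if (p1 < 0 || p1 > 1 || p0 < 0 || p0 > 1) {
    abort("proportions must lie in [0, 1]", class = "tstv_error_argument")
  }
  pooled <- (p1 * n1 + p0 * n0) / (n1 + n0)
  if (pooled <= 0 || pooled >= 1) {
    abort("pooled proportion is 0 or 1; the Z-test variance is zero",
          class = "tstv_error_degenerate_test")
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n0))
  z <- (p1 - p0) / se
  out <- tibble(
    p1 = p1, n1 = n1, p0 = p0, n0 = n0,
    estimate = p1 - p0, se = se, z = z,
    p.value = 2 * pnorm(-abs(z))
  )
  class(out) <- c("tstv_enrichment", class(out))
  out
}

#' One-sample Z-test variant
#'
#' Tests an observed proportion against a fixed null proportion
#' (`z = (p1 - p0) / sqrt(p0 (1 - p0) / n1)`), offered as an alternative
#' reading of a binomial-to-normal enrichment test.
#'
#' @inheritParams two_tailed_z_test
#' @return One-row `tstv_enrichment` tibble (with `n0 = Inf`).
#' @export
one_sample_z_test <- function(p1, n1, p0) {
  if (n1 < 1) abort("`n1` must be >= 1", class = "tstv_error_argument")
  if (p0 <= 0 || p0 >= 1) {
    abort("null proportion must lie strictly in (0, 1)",
          class = "tstv_error_degenerate_test")
  }
  se <- sqrt(p0 * (1 - p0) / n1)
  z <- (p1 - p0) / se
  out <- tibble(
    p1 = p1, n1 = n1, p0 = p0, n0 = Inf,
    estimate = p1 - p0, se = se, z = z,
    p.value = 2 * pnorm(-abs(z))
  )
  class(out) <- c("tstv_enrichment", class(out))
  out
}

#' Transversion enrichment among allele-specific binding variants
#'
#' Computes the Tv fraction among (collapsed) ASB variants and among all
#' (collapsed) tested variants and compares the two with the two-tailed
#' Z-test. The null sample size follows the chosen pooling convention:
#' `"across_groups_mean_n"` uses the mean number of SNPs tested per group
#' (the convention for a dataset pooled across cell lines whose tested
#' sets overlap unknowably), `"union"` uses the total collapsed tested
#' count.
#'
#' @param dataset Tibble of SNP records (`chrom`, `pos`, `ref`, `alt`,
#'   `klass`, `group`, `is_asb`) containing both ASB and non-ASB rows.
#' @param pooling `"across_groups_mean_n"` or `"union"`.
#' @return A one-row `tstv_enrichment` tibble (see [two_tailed_z_test()]).
#' @export
asb_enrichment <- function(dataset,
                           pooling = c("across_groups_mean_n", "union")) {
  pooling <- match.arg(pooling)
  if (!any(dataset$is_asb)) {
    abort("dataset contains no ASB variants", class = "tstv_error_argument")
  }
  collapsed <- collapse_redundant(dataset)
  asb <- filter(collapsed, .data$is_asb)
  p1 <- tv_fraction(asb)
  n1 <- nrow(asb)
  p0 <- tv_fraction(collapsed)
  n0 <- if (pooling == "across_groups_mean_n") {
    mean(count(dataset, .data$group)$n)
  } else {
    nrow(collapsed)
  }
  two_tailed_z_test(p1, n1, p0, n0)
}
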