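#' Read a saturation-mutagenesis activity table
#'
#' TSV with one row per assayed point mutation: `element` (enhancer
#' label), `position` (0-based offset within the element), `ref`, `alt`,
#' and one or more replicate fold-change columns named `rep1`, `rep2`,
#' ... (all strictly positive activity ratios mutant/wild-type).
#'
#' @param path File path.
#' @return Tibble with columns `element`, `position`, `ref`, `alt`,
#'   `klass`, and the replicate columns.
#' @export
read_satmut <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("element", "position", "ref", "alt")
  reps <- grep("^rep[0-9]+$", names(tbl), value = TRUE)
  if (!all(need %in% names(tbl)) || length(reps) == 0) {
    abort("saturation table needs element/position/ref/alt and rep* columns",
          class = "tstv_error_table_format")
  }
  validate_satmut(tbl)
}

#' @rdname read_satmut
#' @param records A saturation-mutagenesis tibble.
#' @export
validate_satmut <- function(records) {
  records <- as_tibble(records)
  reps <- grep("^rep[0-9]+$", names(records), value = TRUE)
  records$ref <- check_bases(records$ref, "ref")
  records$alt <- check_bases(records$alt, "alt")
  if (any(records$ref == records$alt)) {
    abort("alt must differ from ref", class = "tstv_error_data")
  }
  repmat <- as.matrix(records[reps])
  if (any(!is.finite(repmat)) || any(repmat <= 0)) {
    abort("replicate fold changes must be positive and finite",
          class = "tstv_error_data")
  }
  over <- records |>
    count(.data$element, .data$position) |>
    filter(.data$n > 3)
  if (nrow(over) > 0) {
    abort("more than 3 alternative records at one (element, position)",
          class = "tstv_error_data")
  }
  records$klass <- classify_substitution(records$ref, records$alt)
  records
}

#' @rdname read_satmut
#' @param path Output path.
#' @export
write_satmut <- function(records, path) {
  reps <- grep("^rep[0-9]+$", names(records), value = TRUE)
  readr::write_tsv(
    records[c("element", "position", "ref", "alt", reps)], path
  )
  invisible(path)
}

#' Average replicate effects to a |log2 fold change|
#'
#' Replicate fold changes are averaged on the ratio scale first, then the
#' absolute log2 of the mean is taken:
#' `mean_abs_log2fc = |log2(mean(replicates))|`.
#'
#' @param records Saturation-mutagenesis tibble (see [read_satmut()]).
#' @return The records with a `mean_abs_log2fc` column appended.
#' @export
summarize_effects <- function(records) {
  reps <- grep("^rep[0-9]+$", names(records), value = TRUE)
  if (length(reps) == 0) {
    abort("no replicate (rep*) columns found", class = "tstv_error_data")
  }
  repmat <- as.matrix(records[reps])
  mutate(records, mean_abs_log2fc = abs(log2(rowMeans(repmat))))
}

#' Test whether transversions perturb enhancer activity more
#'
#' Ordinary least squares of `mean_abs_log2fc` on a transversion
#' indicator. With `scope = "pooled"`, the element enters as a
#' categorical covariate and the mutation's scaled distance from the
#' element centre (`|position - centre| / element length`) as a location
#' covariate; with `scope = "per_element"` each element is fitted
#' separately with the location covariate only. P-values for the Tv term
#' are one-sided for the alternative beta_TV > 0 (transversions more
#' disruptive); covariate p-values are two-sided.
#'
#' @param records Tibble with `element`, `position`, `klass`, and
#'   `mean_abs_log2fc` (run [summarize_effects()] first if needed).
#' @param scope `"pooled"` or `"per_element"`.
#' @return A `tstv_fit` (pooled) or a named list of `tstv_fit`, one per
#'   element.
#' @export
satmut_ts_tv_test <- function(records, scope = c("pooled", "per_element")) {
  scope <- match.arg(scope)
  if (!"mean_abs_log2fc" %in% names(records)) {
    records <- summarize_effects(records)
  }
  dat <- records |>
    group_by(.data$element) |>
    mutate(
      elem_len = diff(range(.data$position)) + 1,
      center_dist = abs(.data$position - mean(range(.data$position))) /
        .data$elem_len
    ) |>
    ungroup() |>
    mutate(is_tv = as.numeric(.data$klass == "TV"))

  fit_scope <- function(d, label, with_element) {
    if (dplyr::n_distinct(d$klass) < 2) {
      abort("only one substitution class in scope",
            class = "tstv_error_degenerate_design")
    }
    f <- if (with_element) {
      mean_abs_log2fc ~ is_tv + factor(element) + center_dist
    } else {
      mean_abs_log2fc ~ is_tv + center_dist
    }
    fit <- lm(f, data = d)
    coefs <- lm_coef_tbl(fit, keep = c("is_tv", "center_dist"))
    df <- fit$df.residual
    # one-sided p for beta_TV > 0
    coefs <- mutate(coefs, p.value = if_else(
      .data$term == "is_tv",
      pt(.data$statistic, df, lower.tail = FALSE),
      .data$p.value
    ))
    new_tstv_fit(coefs, model_label = label, n_obs = nrow(d),
                 extra = list(one_sided_term = "is_tv", df = df))
  }
  if (scope == "pooled") {
    with_elem <- dplyr::n_distinct(dat$element) > 1
    fit_scope(dat, "satmut |log2FC| ~ TV + element + center_dist [pooled]",
              with_elem)
  } else {
    lapply(split(dat, dat$element), function(d) {
      fit_scope(d, paste0("satmut |log2FC| ~ TV + center_dist [",
                          d$element[1], "]"), FALSE)
    })
  }
}
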