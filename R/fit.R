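#' Construct a regression-result object
#'
#' Light container used by every model-fitting operation in the package.
#' Holds a broom-style coefficient table (one row per term: estimate,
#' standard error, t statistic, p-value) plus bookkeeping. Methods:
#' [tidy()], [glance()], `print()`, [autoplot()].
#'
#' @param coefs Tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @param model_label Short label naming the fitted model.
#' @param n_obs Number of observations used.
#' @param extra Named list of additional metadata (kept as-is in the object).
#' @return An object of class `tstv_fit`.
#' @export
new_tstv_fit <- function(coefs, model_label, n_obs, extra = list()) {
  stopifnot(is.data.frame(coefs))
  structure(
    c(list(coefs = as_tibble(coefs), model_label = model_label,
           n_obs = n_obs), extra),
    class = "tstv_fit"
  )
}

#' @export
print.tstv_fit <- function(x, ...) {
  cat("<tstv_fit> ", x$model_label, "  (n = ", x$n_obs, ")\n", sep = "")
  print(as.data.frame(x$coefs), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname new_tstv_fit
#' @param x A `tstv_fit` object.
#' @param ... Unused.
#' @export
tidy.tstv_fit <- function(x, ...) x$coefs

#' @rdname new_tstv_fit
#' @export
glance.tstv_fit <- function(x, ...) {
  tibble(
    model = x$model_label,
    nobs = x$n_obs,
    n_terms = nrow(x$coefs),
    min_p = suppressWarnings(min(x$coefs$p.value, na.rm = TRUE))
  )
}

# Fixed-effect (within-group demeaned) OLS of y on a single regressor x,
# absorbing a group intercept per level of g. Algebraically identical to
# lm(y ~ x + factor(g)) for the x term (Frisch-Waugh), but tractable when
# g has very many levels. Returns one coefficient row.
fe_ols <- function(y, x, g, term = "x") {
  stopifnot(length(y) == length(x), length(x) == length(g))
  g <- as.character(g)
  yd <- y - ave(y, g)
  xd <- x - ave(x, g)
  sxx <- sum(xd^2)
  if (sxx <= .Machine$double.eps * length(x)) {
    abort(
      "regressor is constant within every group; class effect not estimable",
      class = "tstv_error_degenerate_design"
    )
  }
  beta <- sum(xd * yd) / sxx
  resid <- yd - beta * xd
  df <- length(y) - length(unique(g)) - 1L
  if (df < 1) {
    abort("not enough observations for the fixed-effect fit",
          class = "tstv_error_degenerate_design")
  }
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  tibble(
    term = term, estimate = beta, std.error = se,
    statistic = tval, p.value = 2 * pt(-abs(tval), df)
  )
}

# coefficient table of an lm fit as a tidy tibble (selected terms only)
lm_coef_tbl <- function(fit, keep = NULL) {
  sm <- summary(fit)$coefficients
  out <- tibble(
    term = rownames(sm),
    estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]), p.value = unname(sm[, 4])
  )
  if (!is.null(keep)) out <- filter(out, .data$term %in% keep)
  out
}
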