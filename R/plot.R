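#' Boxplots of shape mutation effects by substitution class
#'
#' @param effects Shape-effect tibble from [run_shape_experiment()].
#' @return A ggplot, faceted by shape parameter.
#' @export
plot_shape_effects <- function(effects) {
  long <- effects |>
    tidyr::pivot_longer(dplyr::starts_with("d_"),
                        names_to = "parameter", values_to = "delta") |>
    mutate(parameter = toupper(sub("^d_", "", .data$parameter)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$klass, y = .data$delta,
                                     fill = .data$klass)) +
    ggplot2::geom_boxplot(outlier.size = 0.3, show.legend = FALSE) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(TS = "grey70", TV = "white")) +
    ggplot2::labs(x = NULL, y = "summed |Δ shape parameter|") +
    ggplot2::theme_bw()
}

#' Boxplots of motif mutation score changes, binned by a covariate
#'
#' @param records Mutation-score records from
#'   [enumerate_mutation_scores()].
#' @param stratify_by `"norm_position"` or `"ic"`.
#' @param n_bins Number of equal-width bins.
#' @return A ggplot.
#' @export
plot_mutation_scores <- function(records,
                                 stratify_by = c("norm_position", "ic"),
                                 n_bins = NULL) {
  stratify_by <- match.arg(stratify_by)
  if (is.null(n_bins)) n_bins <- if (stratify_by == "norm_position") 11L else 20L
  hi <- if (stratify_by == "norm_position") 1 else 2
  breaks <- seq(0, hi, length.out = n_bins + 1)
  records$bin <- factor(
    pmin(pmax(findInterval(records[[stratify_by]], breaks,
                           rightmost.closed = TRUE), 1L), n_bins),
    levels = seq_len(n_bins),
    labels = sprintf("%.2f", (breaks[-1] + breaks[-(n_bins + 1)]) / 2)
  )
  ggplot2::ggplot(records, ggplot2::aes(x = .data$bin, y = .data$delta,
                                        fill = .data$klass)) +
    ggplot2::geom_boxplot(outlier.size = 0.3, position = "dodge") +
    ggplot2::scale_fill_manual(values = c(TS = "grey70", TV = "white")) +
    ggplot2::labs(x = paste0(stratify_by, " (bin midpoint)"),
                  y = "|Δ PSSM score| (bits)", fill = NULL) +
    ggplot2::theme_bw()
}

#' Bar plot of a Tv-enrichment result
#'
#' Shows the transversion percentage in the ASB and tested sets with
#' standard-error bars.
#'
#' @param object A `tstv_enrichment` row (from [asb_enrichment()]), or
#'   several stacked with an identifying `analysis` column.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tstv_enrichment <- function(object, ...) {
  if (!"analysis" %in% names(object)) object$analysis <- "ASB"
  long <- object |>
    tidyr::pivot_longer(c("p1", "p0"), names_to = "set",
                        values_to = "fraction") |>
    mutate(
      set = if_else(.data$set == "p1", "allele-specific", "all tested"),
      n = if_else(.data$set == "allele-specific", .data$n1, .data$n0),
      se_set = sqrt(.data$fraction * (1 - .data$fraction) / .data$n)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$set, y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "grey80", colour = "black", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * (.data$fraction - .data$se_set),
                   ymax = 100 * (.data$fraction + .data$se_set)),
      width = 0.15
    ) +
    ggplot2::facet_wrap(~analysis) +
    ggplot2::labs(x = NULL, y = "% transversions") +
    ggplot2::theme_bw()
}

#' Coefficient plot for a fitted Ts/Tv model
#'
#' @param object A `tstv_fit`.
#' @param ... Unused.
#' @return A ggplot of estimates with +/- 1 s.e.m. bars.
#' @export
autoplot.tstv_fit <- function(object, ...) {
  co <- object$coefs
  ggplot2::ggplot(co, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$estimate - .data$std.error,
                   ymax = .data$estimate + .data$std.error)
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "estimate ± s.e.m.",
                  title = object$model_label) +
    ggplot2::theme_bw()
}

#' Scatter plot of haplotype contrasts against substitution counts
#'
#' @param contrasts Contrast tibble from [build_contrasts()].
#' @return A ggplot with one panel per class.
#' @export
plot_contrasts <- function(contrasts) {
  long <- contrasts |>
    tidyr::pivot_longer(c("n_ts", "n_tv"), names_to = "klass",
                        values_to = "n_diff") |>
    mutate(klass = if_else(.data$klass == "n_ts", "Ts", "Tv"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_diff, y = .data$delta_mag)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.4, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "red",
                         se = FALSE, linewidth = 0.6) +
    ggplot2::facet_wrap(~klass) +
    ggplot2::labs(x = "substitutions vs reference haplotype",
                  y = "|Δ log2 effect size|") +
    ggplot2::theme_bw()
}
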