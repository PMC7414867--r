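#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Mean of the paired measurements against their difference, with the mean
#' bias (solid), its confidence interval (dashed) and the limits of
#' agreement (solid, with dashed confidence bounds).
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "red") +
    ggplot2::geom_hline(yintercept = object$ci_bias, colour = "red", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high), colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = c(object$ci_loa_low, object$ci_loa_high),
                        colour = "darkgreen", linetype = "dashed") +
    ggplot2::labs(x = "Mean of the two measurements",
                  y = "Difference between measurements",
                  title = sprintf("Bland-Altman: bias %.2f, LoA [%.2f, %.2f]",
                                  object$bias, object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Cross-platform score scatter plots
#'
#' One panel per metric, WGS-like platform on the x-axis and array-like on
#' the y-axis, with the OLS fit and the line of equality; the HRD-score
#' panel also shows the classification threshold.
#'
#' @param results_a,results_b HRD result tibbles (a = array-like / y-axis,
#'   b = WGS-like / x-axis), sample-matched.
#' @param threshold HR-status threshold drawn on the HRD-score panel.
#' @return A ggplot (facetted over metrics).
#' @export
plot_score_concordance <- function(results_a, results_b, threshold = 42) {
  results_b <- results_b[match(results_a$sample, results_b$sample), , drop = FALSE]
  long <- function(r, platform) {
    tidyr::pivot_longer(r[, c("sample", "ntai", "hrd_loh", "lst", "hrd_score")],
                        -"sample", names_to = "metric", values_to = platform)
  }
  df <- dplyr::left_join(long(results_a, "array_like"), long(results_b, "wgs_like"),
                         by = c("sample", "metric"))
  thr <- tibble::tibble(metric = "hrd_score", threshold = threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wgs_like, y = .data$array_like)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "blue",
                         linewidth = 0.6, se = TRUE) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(data = thr, ggplot2::aes(xintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = thr, ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "WGS-derived value", y = "Array-derived value") +
    ggplot2::theme_minimal()
}

#' Plot an agreement report
#'
#' Bland-Altman panels for the four metrics of an [build_agreement_report()]
#' result.
#'
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- purrr::imap_dfr(object$bland_altman, function(ba, metric) {
    tibble::tibble(metric = metric, mean = ba$means, diff = ba$diffs,
                   bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$bias), colour = "red") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$loa_low), colour = "darkgreen") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$loa_high), colour = "darkgreen") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "Mean of the two platforms", y = "Difference (WGS-like - array-like)") +
    ggplot2::theme_minimal()
}
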