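#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Bland-Altman analysis
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return One-row tibble with the bias, limits of agreement, their
#'   confidence bounds and the fraction of pairs within the limits.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    n = x$n, bias = x$bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high,
    ci_bias_low = x$ci_bias[1], ci_bias_high = x$ci_bias[2],
    ci_loa_low_low = x$ci_loa_low[1], ci_loa_low_high = x$ci_loa_low[2],
    ci_loa_high_low = x$ci_loa_high[1], ci_loa_high_high = x$ci_loa_high[2],
    fraction_within = x$fraction_within
  )
}

#' @rdname tidy.bland_altman
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) tidy.bland_altman(x, ...)

#' Tidy an agreement report
#'
#' `tidy()` returns the per-metric table (correlation, regression,
#' Bland-Altman parameters, ICC); `glance()` a one-row cohort summary.
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) x$metrics

#' @rdname tidy.agreement_report
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  hrd <- x$metrics[x$metrics$metric == "hrd_score", ]
  tibble::tibble(
    n = x$n,
    pearson_r_hrd = hrd$pearson_r,
    r_squared_hrd = hrd$r_squared,
    icc3_hrd = hrd$icc3,
    bias_hrd = hrd$bias,
    fleiss_kappa = x$classification$fleiss_kappa,
    kappa_p_value = x$classification$kappa_p_value,
    concordance_pct = x$classification$concordance_pct,
    n_discordant = nrow(x$classification$discordant)
  )
}
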