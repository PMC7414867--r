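#' Pearson correlation with simple linear regression
#'
#' Ordinary least-squares fit of `y` on `x` together with the Pearson
#' correlation. By the study's axis convention the WGS-derived values are the
#' explanatory variable `x` and the array-derived values the response `y`.
#' For a simple regression `r_squared` equals the squared Pearson r.
#'
#' @param x Explanatory values (WGS-like platform).
#' @param y Response values (array-like platform), same length.
#' @return One-row tibble: `n`, `pearson_r`, `slope`, `intercept`,
#'   `se_slope`, `se_intercept`, `r_squared`.
#' @export
pearson_with_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant x: regression undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exactly collinear fit; exact agreement is a
  # legitimate input here
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  tibble::tibble(
    n = length(x),
    pearson_r = stats::cor(x, y),
    slope = cf["x", "Estimate"],
    intercept = cf["(Intercept)", "Estimate"],
    se_slope = cf["x", "Std. Error"],
    se_intercept = cf["(Intercept)", "Std. Error"],
    r_squared = sm$r.squared
  )
}

#' Bland-Altman agreement analysis
#'
#' Agreement between two measurement methods via the distribution of their
#' paired differences `d = x - y` (by the study's convention, WGS minus
#' array): mean bias, 95% limits of agreement `bias +/- 1.96 sd(d)`, 95%
#' confidence intervals for the bias (`t * sd/sqrt(n)`) and for each limit
#' (`t * sd * sqrt(3/n)`), and the fraction of pairs falling inside the
#' limits.
#'
#' @param x Minuend measurements (WGS-like platform).
#' @param y Subtrahend measurements (array-like platform), same length.
#' @param conf Confidence level for the intervals (default 0.95).
#' @return An object of class `bland_altman` (a list); see [tidy.bland_altman()].
#' @export
bland_altman <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("Bland-Altman analysis needs at least 3 pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  loa_low <- bias - 1.96 * s
  loa_high <- bias + 1.96 * s
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  structure(
    list(
      n = n, bias = bias, sd_diff = s,
      loa_low = loa_low, loa_high = loa_high,
      ci_bias = c(bias - tq * se_bias, bias + tq * se_bias),
      ci_loa_low = c(loa_low - tq * se_loa, loa_low + tq * se_loa),
      ci_loa_high = c(loa_high - tq * se_loa, loa_high + tq * se_loa),
      fraction_within = mean(d >= loa_low & d <= loa_high),
      conf = conf,
      means = (x + y) / 2, diffs = d
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement (n = ", x$n, ")\n",
      "  bias ", signif(x$bias, 4), " [", signif(x$ci_bias[1], 4), ", ",
      signif(x$ci_bias[2], 4), "]\n",
      "  limits of agreement [", signif(x$loa_low, 4), ", ", signif(x$loa_high, 4), "]\n",
      "  ", signif(100 * x$fraction_within, 4), "% of pairs within limits\n", sep = "")
  invisible(x)
}

#' Intraclass correlation ICC(3,1): two-way mixed, single measure, consistency
#'
#' Computed from the two-way ANOVA mean squares for `n` subjects rated by
#' `k = 2` fixed raters: `(MS_rows - MS_error) / (MS_rows + (k - 1) MS_error)`.
#' The consistency form ignores a fixed offset between raters, so `y = x + c`
#' has ICC 1.
#'
#' @param x,y Ratings of the same subjects by the two raters.
#' @return A single number in \[-1, 1\].
#' @export
icc3 <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("ICC needs at least 3 subjects", call. = FALSE)
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ms_rows <- ss_rows / (n - 1)
  ms_error <- (ss_total - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  if (ms_rows == 0) stop("zero between-subject variance: ICC undefined", call. = FALSE)
  (ms_rows - ms_error) / (ms_rows + (k - 1) * ms_error)
}

#' Fleiss kappa for two raters over two categories
#'
#' Chance-corrected agreement of two binary label sequences (equivalently
#' Scott's pi for two raters), with the standard large-sample z-test
#' two-sided p-value. Undefined (returned as `NA` with a warning) when only
#' one category occurs anywhere.
#'
#' @param labels_a,labels_b Equal-length label vectors over two categories
#'   (e.g. `"deficient"` / `"proficient"`).
#' @return One-row tibble: `n`, `kappa`, `z`, `p_value`.
#' @export
fleiss_kappa_binary <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  cats <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  if (length(cats) > 2) stop("more than two categories", call. = FALSE)
  if (length(cats) < 2) {
    warning("single category across all ratings: kappa undefined")
    return(tibble::tibble(n = n, kappa = NA_real_, z = NA_real_, p_value = NA_real_))
  }
  m <- 2  # raters
  # per-subject count of ratings in the first category
  n1 <- (labels_a == cats[1]) + (labels_b == cats[1])
  p_agree <- mean(n1 == 0 | n1 == m)  # both raters agree
  pj <- c(sum(n1), 2 * n - sum(n1)) / (n * m)
  pe <- sum(pj^2)
  kappa <- (p_agree - pe) / (1 - pe)
  # Fleiss large-sample SE under the null of chance agreement
  se0 <- sqrt(2 * (pe - (2 * m - 3) * pe^2 + 2 * (m - 2) * sum(pj^3))) /
    ((1 - pe) * sqrt(n * m * (m - 1)))
  z <- kappa / se0
  tibble::tibble(n = n, kappa = kappa, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

#' HR-status classification concordance between two platforms
#'
#' Classifies both score vectors at the threshold and reports the percentage
#' of samples on which the platforms agree, together with the discordant
#' samples, their scores and the direction of disagreement.
#'
#' @param scores_a,scores_b Equal-length HRD score vectors (a = array-like,
#'   b = WGS-like by the study's convention).
#' @param threshold Classification threshold (default 42).
#' @param samples Optional sample labels.
#' @return List with `n`, `n_concordant`, `concordance_pct` and `discordant`
#'   (tibble `sample`, `score_a`, `score_b`, `direction`).
#' @export
classification_concordance <- function(scores_a, scores_b, threshold = 42, samples = NULL) {
  stopifnot(length(scores_a) == length(scores_b))
  n <- length(scores_a)
  samples <- samples %||% paste0("sample", seq_len(n))
  st_a <- classify_hr(scores_a, threshold)
  st_b <- classify_hr(scores_b, threshold)
  agree <- st_a == st_b
  disc <- tibble::tibble(
    sample = samples[!agree],
    score_a = scores_a[!agree], score_b = scores_b[!agree],
    direction = ifelse(st_a[!agree] == "deficient",
                       "deficient_by_a_only", "deficient_by_b_only")
  )
  list(n = n, n_concordant = sum(agree),
       concordance_pct = 100 * mean(agree), discordant = disc)
}

#' Compare HRD-score component contributions
#'
#' Two-sided rank tests on the percentage contributions of NtAI, HRD-LOH and
#' LST to the HRD score, plus per-component mean contribution with a 95%
#' t-interval.
#'
#' * `grouping = "platform-paired"`: Wilcoxon signed-rank test of paired
#'   contributions between two platforms (`results_a` vs `results_b`, sample
#'   by sample). With fewer than 5 informative (non-tied) pairs, or whenever
#'   ties permit, the exact null distribution is used; identical paired
#'   contributions give p = 1.
#' * `grouping = "hr-status"`: Wilcoxon rank-sum test between HR-deficient
#'   and HR-proficient samples of a single platform (`results_a`); the
#'   groups are unpaired, so a two-sample rank test is the appropriate form.
#'
#' @param results_a HRD results tibble (from [score_hrd()]).
#' @param results_b Second platform's results (paired mode only).
#' @param grouping `"platform-paired"` or `"hr-status"`.
#' @param conf Confidence level for the mean contributions.
#' @return Tibble with one row per component and group: means, CI bounds and
#'   the test p-value.
#' @export
compare_contributions <- function(results_a, results_b = NULL,
                                  grouping = c("platform-paired", "hr-status"),
                                  conf = 0.95) {
  grouping <- match.arg(grouping)
  comps <- c("pct_ntai", "pct_hrd_loh", "pct_lst")
  mean_ci <- function(v) {
    m <- mean(v)
    if (length(v) < 2 || stats::sd(v) == 0) return(c(m, m, m))
    half <- stats::qt(1 - (1 - conf) / 2, length(v) - 1) * stats::sd(v) / sqrt(length(v))
    c(m, m - half, m + half)
  }
  if (grouping == "platform-paired") {
    stopifnot(!is.null(results_b), nrow(results_a) == nrow(results_b))
    purrr::map_dfr(comps, function(cc) {
      a <- results_a[[cc]]; b <- results_b[[cc]]
      d <- a - b
      p <- if (all(d == 0)) 1 else {
        suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            exact = sum(d != 0) < 50)$p.value)
      }
      ma <- mean_ci(a); mb <- mean_ci(b)
      tibble::tibble(
        component = sub("^pct_", "", cc),
        mean_a = ma[1], ci_low_a = ma[2], ci_high_a = ma[3],
        mean_b = mb[1], ci_low_b = mb[2], ci_high_b = mb[3],
        test = "wilcoxon_signed_rank", p_value = p
      )
    })
  } else {
    stopifnot(is.null(results_b))
    grp <- results_a$hr_status
    if (length(unique(grp)) < 2) stop("hr-status grouping needs both classes present", call. = FALSE)
    purrr::map_dfr(comps, function(cc) {
      a <- results_a[[cc]][grp == "deficient"]
      b <- results_a[[cc]][grp == "proficient"]
      p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
      ma <- mean_ci(a); mb <- mean_ci(b)
      tibble::tibble(
        component = sub("^pct_", "", cc),
        mean_a = ma[1], ci_low_a = ma[2], ci_high_a = ma[3],
        mean_b = mb[1], ci_low_b = mb[2], ci_high_b = mb[3],
        test = "wilcoxon_rank_sum", p_value = p
      )
    })
  }
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS statistic with the asymptotic p-value, used to
#' compare the distributions of a score across platforms.
#'
#' @param values_a,values_b Numeric samples (each of length >= 3).
#' @return One-row tibble: `D`, `p_value`.
#' @export
ks_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 3, length(values_b) >= 3)
  kt <- suppressWarnings(stats::ks.test(values_a, values_b, exact = FALSE))
  tibble::tibble(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Full paired-cohort agreement report
#'
#' Runs the complete agreement battery over two platforms' HRD results,
#' sample-matched by the `sample` column: per metric (NtAI, HRD-LOH, LST,
#' HRD score) Pearson correlation with regression, Bland-Altman analysis and
#' ICC(3,1); HR-status classification concordance with Fleiss kappa; per-
#' metric Kolmogorov-Smirnov distribution comparison; and the paired
#' component-contribution comparison.
#'
#' By the study's convention `results_a` is the array-like platform
#' (regression response, subtrahend of differences) and `results_b` the
#' WGS-like platform (explanatory axis, minuend).
#'
#' @param results_a,results_b HRD results tibbles from [score_hrd()] with
#'   matching samples.
#' @param params A [scoring_params()] list (supplies the HR threshold).
#' @return An object of class `agreement_report`; see
#'   [tidy.agreement_report()] and [glance.agreement_report()].
#' @export
build_agreement_report <- function(results_a, results_b, params = scoring_params()) {
  stopifnot(is.data.frame(results_a), is.data.frame(results_b))
  results_b <- results_b[match(results_a$sample, results_b$sample), , drop = FALSE]
  if (anyNA(results_b$sample)) stop("cohorts do not share the same samples", call. = FALSE)
  if (nrow(results_a) < 3) stop("agreement analysis needs at least 3 paired samples", call. = FALSE)
  metrics <- c(ntai = "ntai", hrd_loh = "hrd_loh", lst = "lst", hrd_score = "hrd_score")
  ba <- list(); per_metric <- list(); ks <- list()
  for (mname in names(metrics)) {
    a <- results_a[[metrics[mname]]]
    b <- results_b[[metrics[mname]]]
    reg <- pearson_with_regression(x = b, y = a)
    bam <- bland_altman(x = b, y = a)
    ba[[mname]] <- bam
    per_metric[[mname]] <- dplyr::bind_cols(
      tibble::tibble(metric = mname), reg,
      tibble::tibble(icc3 = icc3(a, b), bias = bam$bias, sd_diff = bam$sd_diff,
                     loa_low = bam$loa_low, loa_high = bam$loa_high,
                     fraction_within = bam$fraction_within)
    )
    ks[[mname]] <- dplyr::bind_cols(tibble::tibble(metric = mname), ks_compare(a, b))
  }
  cls <- classification_concordance(results_a$hrd_score, results_b$hrd_score,
                                    threshold = params$hr_threshold,
                                    samples = results_a$sample)
  fk <- fleiss_kappa_binary(classify_hr(results_a$hrd_score, params$hr_threshold),
                            classify_hr(results_b$hrd_score, params$hr_threshold))
  structure(
    list(
      n = nrow(results_a),
      metrics = dplyr::bind_rows(per_metric),
      bland_altman = ba,
      classification = list(
        fleiss_kappa = fk$kappa, kappa_z = fk$z, kappa_p_value = fk$p_value,
        concordance_pct = cls$concordance_pct, n_concordant = cls$n_concordant,
        discordant = cls$discordant, threshold = params$hr_threshold
      ),
      ks = dplyr::bind_rows(ks),
      contributions = compare_contributions(results_a, results_b, "platform-paired")
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Paired-platform agreement report (n = ", x$n, ")\n", sep = "")
  print(x$metrics[, c("metric", "pearson_r", "r_squared", "icc3", "bias", "fraction_within")])
  cat("HR-status concordance ", signif(x$classification$concordance_pct, 4),
      "% (Fleiss kappa ", signif(x$classification$fleiss_kappa, 3), ", p ",
      format(x$classification$kappa_p_value, digits = 3), "); ",
      nrow(x$classification$discordant), " discordant sample(s)\n", sep = "")
  invisible(x)
}
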