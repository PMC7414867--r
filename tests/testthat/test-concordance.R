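test_that("regression recovers exact linear relations and the 3-point closed form", {
  x <- c(1, 2, 3, 4)
  r <- pearson_with_regression(x, x)
  expect_equal(unlist(r[c("pearson_r", "slope", "intercept", "r_squared")]),
               c(pearson_r = 1, slope = 1, intercept = 0, r_squared = 1))
  r <- pearson_with_regression(x, 2 * x + 3)
  expect_equal(r$slope, 2); expect_equal(r$intercept, 3); expect_equal(r$pearson_r, 1)
  # closed-form OLS on three points: slope Sxy/Sxx = 3/2, intercept ybar - slope*xbar
  r <- pearson_with_regression(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$slope, 1.5)
  expect_equal(r$intercept, 7 / 3 - 1.5 * 2)
  expect_equal(r$pearson_r, 3 / sqrt(2 * 42 / 9), tolerance = 1e-12)
  expect_error(pearson_with_regression(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("R-squared equals squared Pearson r on random inputs", {
  set.seed(8)
  for (i in 1:25) {
    x <- stats::rnorm(20); y <- 0.5 * x + stats::rnorm(20)
    r <- pearson_with_regression(x, y)
    expect_equal(r$r_squared, r$pearson_r^2, tolerance = 1e-12)
  }
})

test_that("Bland-Altman parameters follow the direct formulas", {
  y <- c(4, 3, 2, 1)
  ba <- bland_altman(y, y)
  expect_equal(ba$bias, 0); expect_equal(ba$loa_low, 0); expect_equal(ba$fraction_within, 1)
  ba <- bland_altman(y + 2, y)
  expect_equal(ba$bias, 2); expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(2, 2))
  # d = (-1, 0, 1, 2)
  ba <- bland_altman(c(0, 3, 4, 7), c(1, 3, 3, 5))
  expect_equal(ba$bias, 0.5)
  expect_equal(ba$sd_diff, sqrt(5 / 3), tolerance = 1e-12)
  s <- sqrt(5 / 3); tq <- stats::qt(0.975, 3)
  expect_equal(ba$loa_high, 0.5 + 1.96 * s)
  expect_equal(ba$ci_bias, c(0.5 - tq * s / 2, 0.5 + tq * s / 2))
  expect_equal(ba$ci_loa_low, (0.5 - 1.96 * s) + c(-1, 1) * tq * s * sqrt(3 / 4))
  expect_error(bland_altman(1:2, 2:3), "at least 3")
})

test_that("about 95% of Gaussian differences fall inside the limits of agreement", {
  set.seed(1234)
  x <- stats::rnorm(10000); y <- x - stats::rnorm(10000, 0.3, 2)
  ba <- bland_altman(x, y)
  expect_gt(ba$fraction_within, 0.92)
  expect_lt(ba$fraction_within, 0.98)
})

test_that("ICC(3,1) matches the aov mean-squares oracle and ignores rater offsets", {
  x <- c(1, 2, 3, 4)
  expect_equal(icc3(x, x), 1)
  expect_equal(icc3(x, x + 5), 1)
  expect_equal(icc3(x, c(2, 1, 4, 3)), oracle_icc3_aov(x, c(2, 1, 4, 3)), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:30) {
    a <- stats::rnorm(8); b <- a + stats::rnorm(8, 0, 0.7)
    expect_equal(icc3(a, b), oracle_icc3_aov(a, b), tolerance = 1e-10)
  }
  expect_error(icc3(c(1, 1, 1), c(1, 1, 1)), "zero between-subject")
})

test_that("Fleiss kappa matches the contingency-table oracle on all small tables", {
  mk <- function(a, b, c, d) {
    list(r1 = rep(c("def", "def", "prof", "prof"), c(a, b, c, d)),
         r2 = rep(c("def", "prof", "def", "prof"), c(a, b, c, d)))
  }
  # exhaustive over tables with all margins <= 10
  for (a in 0:10) for (b in 0:10) for (c in 0:10) for (d in 0:10) {
    n <- a + b + c + d
    if (n < 2 || n > 14) next
    if (a + b + c == 0 || b + c + d == 0) next  # single category: undefined
    l <- mk(a, b, c, d)
    expect_equal(fleiss_kappa_binary(l$r1, l$r2)$kappa,
                 oracle_fleiss_2x2(a, b, c, d), tolerance = 1e-12,
                 info = paste(a, b, c, d))
  }
  # chance-only agreement and perfect agreement
  l <- mk(25, 25, 25, 25)
  expect_equal(fleiss_kappa_binary(l$r1, l$r2)$kappa, 0)
  l <- mk(30, 0, 0, 30)
  fk <- fleiss_kappa_binary(l$r1, l$r2)
  expect_equal(fk$kappa, 1)
  expect_lt(fk$p_value, 1e-10)
  # the derived mixed table, against the same spreadsheet formula
  l <- mk(30, 3, 2, 32)
  expect_equal(fleiss_kappa_binary(l$r1, l$r2)$kappa, oracle_fleiss_2x2(30, 3, 2, 32))
  expect_warning(out <- fleiss_kappa_binary(rep("def", 5), rep("def", 5)), "single category")
  expect_true(is.na(out$kappa))
})

test_that("classification concordance reports directions of discordance", {
  cc <- classification_concordance(c(43, 42, 44, 36, 36), c(41, 38, 39, 44, 42))
  expect_equal(cc$concordance_pct, 0)
  expect_equal(nrow(cc$discordant), 5)
  expect_equal(sum(cc$discordant$direction == "deficient_by_a_only"), 3)
  expect_equal(sum(cc$discordant$direction == "deficient_by_b_only"), 2)
  cc <- classification_concordance(c(50, 10, 42), c(50, 10, 42))
  expect_equal(cc$concordance_pct, 100)
  expect_equal(nrow(cc$discordant), 0)
  # a threshold tie on both sides is concordant-deficient
  cc <- classification_concordance(42, 42)
  expect_equal(cc$n_concordant, 1)
})

test_that("exact signed-rank p-values match full sign-pattern enumeration", {
  set.seed(77)
  for (n in c(5, 7, 9, 10)) {
    for (rep in 1:5) {
      d <- round(stats::rnorm(n, 0.4, 1), 3)
      d <- d[d != 0]
      if (length(d) < 2) next
      p_pkg <- stats::wilcox.test(d, exact = TRUE)$p.value
      expect_equal(p_pkg, oracle_signed_rank_exact(d), tolerance = 1e-12,
                   info = paste("n =", n, "rep", rep))
    }
  }
})

test_that("contribution comparisons detect shifts and return p = 1 on identity", {
  mk_res <- function(pct, status = "deficient") {
    k <- nrow(pct)
    tibble::tibble(sample = paste0("s", 1:k), ntai = 1, hrd_loh = 1, lst = 1,
                   hrd_score = 3, hr_status = status,
                   pct_ntai = pct[, 1], pct_hrd_loh = pct[, 2], pct_lst = pct[, 3])
  }
  set.seed(3)
  base <- cbind(stats::rnorm(20, 38, 4), stats::rnorm(20, 27, 4), stats::rnorm(20, 35, 4))
  same <- compare_contributions(mk_res(base), mk_res(base))
  expect_true(all(same$p_value == 1))
  shifted <- base; shifted[, 2] <- shifted[, 2] + 15
  out <- compare_contributions(mk_res(base), mk_res(shifted))
  expect_lt(out$p_value[out$component == "hrd_loh"], 0.05)
  # constant contributions give a zero-width CI at the constant
  const <- cbind(rep(40, 6), rep(25, 6), rep(35, 6))
  out <- compare_contributions(mk_res(const), mk_res(const))
  expect_equal(out$mean_a, c(40, 25, 35))
  expect_equal(out$ci_low_a, out$ci_high_a)
  # hr-status grouping uses an unpaired rank-sum test
  res <- dplyr::bind_rows(mk_res(base, "deficient"), mk_res(shifted, "proficient"))
  out <- compare_contributions(res, grouping = "hr-status")
  expect_equal(unique(out$test), "wilcoxon_rank_sum")
  expect_lt(out$p_value[out$component == "hrd_loh"], 0.05)
})

test_that("KS comparison follows the ECDF arithmetic", {
  ident <- ks_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ident$D, 0); expect_equal(ident$p_value, 1)
  expect_equal(ks_compare(1:50, 51:100)$D, 1)
  expect_equal(ks_compare(c(1, 2, 3, 4), c(1, 2, 3, 10))$D, 0.25)
})

test_that("the full agreement report is coherent on identical cohorts", {
  # synthetic result table spanning both HR classes at the default threshold
  set.seed(11)
  comp <- matrix(rpois(24, c(3, 2, 3, 20, 15, 25)), ncol = 3, byrow = TRUE)
  score <- rowSums(comp)
  res <- tibble::tibble(
    sample = sprintf("s%02d", 1:8),
    ntai = comp[, 1], hrd_loh = comp[, 2], lst = comp[, 3],
    hrd_score = score, hr_status = classify_hr(score),
    pct_ntai = 100 * comp[, 1] / score, pct_hrd_loh = 100 * comp[, 2] / score,
    pct_lst = 100 * comp[, 3] / score)
  stopifnot(length(unique(res$hr_status)) == 2)
  rep0 <- build_agreement_report(res, res)
  g <- glance(rep0)
  expect_equal(g$pearson_r_hrd, 1)
  expect_equal(g$icc3_hrd, 1)
  expect_equal(g$concordance_pct, 100)
  expect_equal(g$fleiss_kappa, 1)
  expect_equal(nrow(tidy(rep0)), 4)
  expect_error(build_agreement_report(res[1, ], res[1, ]), "at least 3")
})
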