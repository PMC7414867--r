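# synthetic generator checks run on a reduced three-chromosome genome where
# placement geometry still allows all event classes
sb <- toy_build(c(A = 249e6, B = 180e6, C = 140e6),
                cen_frac_lo = 0.45, cen_frac_hi = 0.48)

test_that("truth simulation is deterministic and records its event counts", {
  t1 <- simulate_true_profile(sb, "hr_deficient", seed = 3)
  t2 <- simulate_true_profile(sb, "hr_deficient", seed = 3)
  expect_identical(t1$profile, t2$profile)
  expect_identical(t1$events, t2$events)
  t3 <- simulate_true_profile(sb, "hr_deficient", seed = 4)
  expect_false(identical(t1$profile, t3$profile))
  # recorded counts match the event table
  expect_equal(sum(t1$events$type == "tai"), t1$truth$n_tai)
  expect_equal(sum(t1$events$type == "loh"), t1$truth$n_loh)
  expect_equal(2 * sum(t1$events$type == "lst"), t1$truth$n_lst_breaks)
})

test_that("the scored truth is at least the sum of injected qualifying events", {
  for (s in 1:5) {
    t <- suppressMessages(simulate_true_profile(sb, "hr_deficient", seed = 100 + s))
    r <- score_hrd(t$profile, sb)
    expect_equal(r$ntai, t$truth$n_tai)
    expect_equal(r$hrd_loh, t$truth$n_loh)
    expect_gte(r$lst, t$truth$n_lst_breaks)
    expect_gte(r$hrd_score, t$truth$n_tai + t$truth$n_loh + t$truth$n_lst_breaks)
  }
})

test_that("a zero-noise view is the truth; full miss probability erases all events", {
  t <- simulate_true_profile(sb, "hr_deficient", seed = 9, sample_id = "S")
  v <- render_platform_view(t, platform_model("clean"), seed = 1, build = sb, sample_id = "S")
  expect_identical(as.data.frame(v), as.data.frame(t$profile))
  v1 <- render_platform_view(t, platform_model("blind", p_miss_event = 1),
                             seed = 1, build = sb, sample_id = "S")
  expect_true(all(v1$n_major == 1 & v1$n_minor == 1))
  expect_equal(score_hrd(v1, sb)$hrd_score, 0L)
})

test_that("small jitter leaves component scores equal to the truth", {
  ok <- 0
  for (s in 1:25) {
    t <- suppressMessages(simulate_true_profile(sb, "hr_deficient", seed = 200 + s, sample_id = "S"))
    v <- render_platform_view(t, platform_model("jit", breakpoint_jitter_sd = 1e4),
                              seed = 300 + s, build = sb, sample_id = "S")
    if (identical(score_hrd(v, sb)[, 2:5], score_hrd(t$profile, sb)[, 2:5])) ok <- ok + 1
  }
  # 10 kb jitter is far below every rule margin, so scores virtually never move
  expect_gte(ok, 24)
})

test_that("probe tracks reflect copy state with zero noise and grow noisier with log2 sd", {
  seg <- tibble::tibble(sample = "S", chrom = "A", start = 1, end = 10e6,
                        n_major = 1, n_minor = 1)
  m0 <- platform_model("quiet", probe_spacing = 1e5)
  tr <- render_probe_track(seg, m0, seed = 1)
  expect_true(all(tr$log2 == 0))
  expect_true(all(tr$baf == 0.5))
  expect_equal(dlrs(tr), 0)
  # monotone noise response over seed averages
  noisy_dlrs <- function(sd) {
    mean(vapply(1:20, function(s) {
      dlrs(render_probe_track(seg, platform_model("n", probe_spacing = 1e5,
                                                  log2_noise_sd = sd), seed = s))
    }, numeric(1)))
  }
  d1 <- noisy_dlrs(0.05); d2 <- noisy_dlrs(0.15); d3 <- noisy_dlrs(0.35)
  expect_lt(d1, d2); expect_lt(d2, d3)
  # dlrs estimates the per-probe noise sd
  expect_equal(d2, 0.15, tolerance = 0.05)
})

test_that("shipped presets keep the coverage-noise ordering", {
  pr <- platform_presets()
  tiers <- pr[c("wgs70x", "wgs30x", "wgs15x", "wgs10x")]
  spur <- vapply(tiers, function(m) m$p_spurious_breakpoint, numeric(1))
  lnsd <- vapply(tiers, function(m) m$log2_noise_sd, numeric(1))
  expect_true(all(diff(spur) >= 0))
  expect_true(all(diff(lnsd) >= 0))
})

test_that("cohort bundles are seed-reproducible and score both platforms", {
  c1 <- suppressMessages(simulate_cohort(sb, n_samples = 6, deficient_fraction = 0.5, seed = 5))
  c2 <- suppressMessages(simulate_cohort(sb, n_samples = 6, deficient_fraction = 0.5, seed = 5))
  expect_identical(c1$scores, c2$scores)
  expect_equal(names(c1$views), c("array", "wgs70x"))
  expect_equal(nrow(c1$truth_scores), 6)
  expect_equal(c1$truth_scores$sample, c1$scores$array$sample)
  # zero-noise models give perfect cross-platform agreement
  quiet <- list(a = platform_model("a"), b = platform_model("b"))
  c3 <- suppressMessages(simulate_cohort(sb, n_samples = 6, models = quiet, seed = 8))
  expect_equal(c3$scores$a$hrd_score, c3$scores$b$hrd_score)
  expect_equal(c3$scores$a$hrd_score, c3$truth_scores$hrd_score)
})
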