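# toy genome with two 100/80 Mb chromosomes, centromeres mid-chromosome
tb <- toy_build(c(A = 100e6, B = 80e6))

prof <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(sample = "S", chrom = r[[1]], start = r[[2]], end = r[[3]],
                   n_major = r[[4]], n_minor = r[[5]])
  }))
}

test_that("normalization merges, splits at the centromere, and is idempotent", {
  # two adjacent 1+1 segments merge
  p <- prof(list("A", 1, 10e6, 1, 1), list("A", 10e6 + 1, 30e6, 1, 1))
  n <- normalize_profile(p, tb)
  expect_equal(nrow(n), 1)
  expect_equal(n$end, 30e6)
  # a segment spanning the centromere splits into p and q parts
  p <- prof(list("A", 1, 100e6, 2, 1))
  n <- normalize_profile(p, tb)
  expect_equal(nrow(n), 2)
  expect_equal(n$end[1], 45e6 - 1)   # centromere [45e6, 55e6]
  expect_equal(n$start[2], 55e6 + 1)
  expect_equal(as.data.frame(normalize_profile(n, tb)), as.data.frame(n))
  # beyond-chromosome-end segments are an error
  expect_error(normalize_profile(prof(list("A", 1, 101e6, 1, 1)), tb), "beyond")
})

test_that("NtAI counts telomeric non-centromere-crossing imbalance", {
  # all-1+1 genome: nothing imbalanced
  p <- prof(list("A", 1, 100e6, 1, 1), list("B", 1, 80e6, 1, 1))
  expect_equal(score_ntai(p, tb)$ntai, 0L)
  # terminal 8 Mb 2+1 on the p-arm, remainder 1+1
  p <- prof(list("A", 1, 8e6, 2, 1), list("A", 8e6 + 1, 100e6, 1, 1))
  expect_equal(score_ntai(p, tb)$ntai, 1L)
  # whole-chromosome 2+1: excluded
  p <- prof(list("A", 1, 100e6, 2, 1))
  expect_equal(score_ntai(p, tb)$ntai, 0L)
  # ... and remains excluded when the caller split it at the centromere
  p <- prof(list("A", 1, 45e6 - 1, 2, 1), list("A", 55e6 + 1, 100e6, 2, 1))
  expect_equal(score_ntai(p, tb)$ntai, 0L)
  # terminal segment crossing the centromere: excluded
  p <- prof(list("A", 1, 70e6, 2, 1), list("A", 70e6 + 1, 100e6, 1, 1))
  expect_equal(score_ntai(p, tb)$ntai, 0L)
  # both chromosome ends imbalanced: two events
  p <- prof(list("A", 1, 8e6, 2, 1), list("A", 8e6 + 1, 90e6, 1, 1),
            list("A", 90e6 + 1, 100e6, 3, 1))
  expect_equal(score_ntai(p, tb)$ntai, 2L)
  # minimum-length knob
  pars <- scoring_params(ntai_min_len = 10e6)
  p <- prof(list("A", 1, 8e6, 2, 1), list("A", 8e6 + 1, 100e6, 1, 1))
  expect_equal(score_ntai(p, tb, pars)$ntai, 0L)
})

test_that("HRD-LOH counts interstitial LOH regions over 15 Mb", {
  flank <- function(s, e) list("A", s, e, 1, 1)
  # interstitial 16 Mb 1+0: one region
  p <- prof(flank(1, 20e6), list("A", 20e6 + 1, 36e6, 1, 0), flank(36e6 + 1, 100e6))
  expect_equal(score_hrd_loh(p, tb)$hrd_loh, 1L)
  # 14 Mb: below the cutoff
  p <- prof(flank(1, 20e6), list("A", 20e6 + 1, 34e6, 1, 0), flank(34e6 + 1, 100e6))
  expect_equal(score_hrd_loh(p, tb)$hrd_loh, 0L)
  # exactly 15 Mb: cutoff is exclusive
  p <- prof(flank(1, 20e6), list("A", 20e6 + 1, 35e6, 1, 0), flank(35e6 + 1, 100e6))
  expect_equal(score_hrd_loh(p, tb)$hrd_loh, 0L)
  # whole-chromosome LOH: excluded
  p <- prof(list("A", 1, 100e6, 1, 0))
  expect_equal(score_hrd_loh(p, tb)$hrd_loh, 0L)
  # adjacent LOH runs with different n_major merge into one region
  p <- prof(flank(1, 20e6), list("A", 20e6 + 1, 30e6, 1, 0),
            list("A", 30e6 + 1, 40e6, 2, 0), flank(40e6 + 1, 100e6))
  expect_equal(score_hrd_loh(p, tb)$hrd_loh, 1L)
  # a homozygous deletion terminates the run: two sub-threshold pieces
  p <- prof(flank(1, 20e6), list("A", 20e6 + 1, 30e6, 1, 0),
            list("A", 30e6 + 1, 31e6, 0, 0),
            list("A", 31e6 + 1, 41e6, 1, 0), flank(41e6 + 1, 100e6))
  expect_equal(score_hrd_loh(p, tb)$hrd_loh, 0L)
})

test_that("LST counts smoothed adjacent-state breaks with 10 Mb flanks", {
  # contiguous 20 (1+1) | 30 (2+1) | 25 (2+2) Mb on one arm-sized chromosome
  wide <- toy_build(c(W = 80e6), cen_frac_lo = 0.95, cen_frac_hi = 0.96)
  p <- prof(list("W", 1, 20e6, 1, 1), list("W", 20e6 + 1, 50e6, 2, 1),
            list("W", 50e6 + 1, 75e6, 2, 2))
  expect_equal(score_lst(p, wide)$lst, 2L)
  # 2 Mb interruption is smoothed away and the flanks re-merge
  p <- prof(list("W", 1, 20e6, 1, 1), list("W", 20e6 + 1, 22e6, 3, 1),
            list("W", 22e6 + 1, 52e6, 1, 1))
  expect_equal(score_lst(p, wide)$lst, 0L)
  # flank below 10 Mb does not count
  p <- prof(list("W", 1, 9e6, 1, 1), list("W", 9e6 + 1, 39e6, 2, 2))
  expect_equal(score_lst(p, wide)$lst, 0L)
  # breaks are counted per arm: a state change across the centromere is not an LST
  p <- prof(list("A", 1, 44e6, 1, 1), list("A", 44e6 + 1, 100e6, 2, 2))
  expect_equal(score_lst(p, tb)$lst, 0L)
})

test_that("threshold classification puts ties at 42 with the deficient class", {
  expect_equal(classify_hr(c(43, 41, 42, 0)),
               c("deficient", "proficient", "deficient", "proficient"))
  expect_error(classify_hr(-1))
})

test_that("the HRD score is the component sum with consistent contributions", {
  set.seed(7)
  b <- toy_build(c(A = 100e6, B = 80e6, C = 120e6))
  for (i in 1:20) {
    p <- random_profile(b)
    r <- score_hrd(p, b)
    expect_equal(r$hrd_score, r$ntai + r$hrd_loh + r$lst)
    expect_equal(r$hr_status, classify_hr(r$hrd_score))
    if (r$hrd_score > 0) {
      expect_equal(r$pct_ntai + r$pct_hrd_loh + r$pct_lst, 100)
    } else {
      expect_equal(c(r$pct_ntai, r$pct_hrd_loh, r$pct_lst), c(0, 0, 0))
    }
  }
  # empty (all reference) genome scores 0 and equal components split 33.33%
  p <- prof(list("A", 1, 100e6, 1, 1))
  r <- score_hrd(p, tb)
  expect_equal(r$hrd_score, 0L)
  expect_equal(r$hr_status, "proficient")
})
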