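# Brute-force oracles and toy fixtures, deliberately written as literal
# rule enumerations independent of the package's implementation paths.

toy_build <- function(lens = c(A = 100e6, B = 80e6),
                      cen_frac_lo = 0.45, cen_frac_hi = 0.55) {
  genome_build(
    tibble::tibble(chrom = names(lens), length = unname(lens)),
    tibble::tibble(chrom = names(lens),
                   cen_start = floor(unname(lens) * cen_frac_lo),
                   cen_end = floor(unname(lens) * cen_frac_hi)),
    name = "toy"
  )
}

# tiny build for exhaustive position-level checks
micro_build <- function(len = 100, cen = c(41, 60)) {
  genome_build(tibble::tibble(chrom = "M", length = len),
               tibble::tibble(chrom = "M", cen_start = cen[1], cen_end = cen[2]),
               name = "micro")
}

# random segment profile on a toy build: <= max_seg segments per chromosome,
# contiguous except for occasional gaps, states drawn from small allele counts
random_profile <- function(build, max_seg = 12, p_gap = 0.2, sample_id = "R") {
  rows <- list()
  for (ci in seq_len(nrow(build$chromosomes))) {
    ch <- build$chromosomes$chrom[ci]
    len <- build$chromosomes$length[ci]
    k <- sample(1:max_seg, 1)
    cuts <- sort(sample.int(len - 1, k - 1))
    bounds <- cbind(c(1, cuts + 1), c(cuts, len))
    for (i in seq_len(k)) {
      if (stats::runif(1) < p_gap) next
      nmaj <- sample(0:3, 1)
      nmin <- sample(0:nmaj, 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = sample_id, chrom = ch,
        start = bounds[i, 1], end = bounds[i, 2],
        n_major = nmaj, n_minor = nmin)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(sample = sample_id, chrom = build$chromosomes$chrom[1],
                          start = 1, end = build$chromosomes$length[1],
                          n_major = 1, n_minor = 1))
  }
  dplyr::bind_rows(rows)
}

# --- literal-rule scar oracles ------------------------------------------------

# same-state coalescing used by the oracles: walk rows, join when gap is zero
# or the skipped interval sits inside the centromere
oracle_coalesce <- function(df, build) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  out <- list()
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, , drop = FALSE]
    cen <- build$centromeres[build$centromeres$chrom == ch, ]
    cur <- s[1, , drop = FALSE]
    if (nrow(s) > 1) for (i in 2:nrow(s)) {
      gap_lo <- cur$end + 1; gap_hi <- s$start[i] - 1
      gap_ok <- gap_hi < gap_lo ||
        (gap_lo >= cen$cen_start && gap_hi <= cen$cen_end)
      if (gap_ok && s$n_major[i] == cur$n_major && s$n_minor[i] == cur$n_minor) {
        cur$end <- s$end[i]
      } else {
        out[[length(out) + 1]] <- cur
        cur <- s[i, , drop = FALSE]
      }
    }
    out[[length(out) + 1]] <- cur
  }
  dplyr::bind_rows(out)
}

oracle_ntai <- function(df, build, params = scoring_params()) {
  v <- oracle_coalesce(oracle_normalize(df, build), build)
  count <- 0
  for (ch in unique(v$chrom)) {
    s <- v[v$chrom == ch, , drop = FALSE]
    cen <- build$centromeres[build$centromeres$chrom == ch, ]
    for (i in unique(c(1, nrow(s)))) {
      seg <- s[i, ]
      ai <- seg$n_major != seg$n_minor
      crosses <- seg$start < cen$cen_start && seg$end > cen$cen_end
      whole <- nrow(s) == 1
      long_enough <- (seg$end - seg$start + 1) >= params$ntai_min_len
      if (ai && !crosses && !whole && long_enough) count <- count + 1
    }
  }
  count
}

oracle_hrd_loh <- function(df, build, params = scoring_params()) {
  v <- oracle_coalesce(oracle_normalize(df, build), build)
  count <- 0
  for (ch in unique(v$chrom)) {
    s <- v[v$chrom == ch, , drop = FALSE]
    cen <- build$centromeres[build$centromeres$chrom == ch, ]
    loh <- s$n_minor == 0 & s$n_major >= 1
    i <- 1
    while (i <= nrow(s)) {
      if (!loh[i]) { i <- i + 1; next }
      j <- i
      while (j < nrow(s) && loh[j + 1]) {
        gap_lo <- s$end[j] + 1; gap_hi <- s$start[j + 1] - 1
        gap_ok <- gap_hi < gap_lo ||
          (gap_lo >= cen$cen_start && gap_hi <= cen$cen_end)
        if (!gap_ok) break
        j <- j + 1
      }
      reg_len <- s$end[j] - s$start[i] + 1
      whole <- i == 1 && j == nrow(s)
      if (!whole && reg_len > params$loh_min_len) count <- count + 1
      i <- j + 1
    }
  }
  count
}

oracle_lst <- function(df, build, params = scoring_params()) {
  norm <- oracle_normalize(df, build)
  count <- 0
  for (ch in unique(norm$chrom)) {
    cen <- build$centromeres[build$centromeres$chrom == ch, ]
    for (side in c("p", "q")) {
      s <- norm[norm$chrom == ch, , drop = FALSE]
      s <- if (side == "p") s[s$end < cen$cen_start, , drop = FALSE]
      else s[s$start > cen$cen_end, , drop = FALSE]
      if (nrow(s) == 0) next
      s <- oracle_smooth(s, params$lst_smooth_len)
      if (nrow(s) < 2) next
      for (i in seq_len(nrow(s) - 1)) {
        diff_state <- s$n_major[i] != s$n_major[i + 1] || s$n_minor[i] != s$n_minor[i + 1]
        len_i <- s$end[i] - s$start[i] + 1
        len_j <- s$end[i + 1] - s$start[i + 1] + 1
        gap <- s$start[i + 1] - s$end[i] - 1
        if (diff_state && len_i >= params$lst_min_flank &&
            len_j >= params$lst_min_flank && gap <= params$lst_max_gap) {
          count <- count + 1
        }
      }
    }
  }
  count
}

oracle_normalize <- function(df, build) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(df))) {
    seg <- df[i, , drop = FALSE]
    cen <- build$centromeres[build$centromeres$chrom == seg$chrom, ]
    if (seg$start < cen$cen_start) {
      p <- seg; p$end <- min(seg$end, cen$cen_start - 1)
      out[[length(out) + 1]] <- p
    }
    if (seg$end > cen$cen_end) {
      q <- seg; q$start <- max(seg$start, cen$cen_end + 1)
      out[[length(out) + 1]] <- q
    }
  }
  x <- dplyr::bind_rows(out)
  x[order(x$chrom, x$start), , drop = FALSE]
}

oracle_smooth <- function(s, smooth_len) {
  repeat {
    # merge same-state neighbours closer than smooth_len
    repeat {
      merged <- FALSE
      if (nrow(s) > 1) for (i in seq_len(nrow(s) - 1)) {
        gap <- s$start[i + 1] - s$end[i] - 1
        if (gap < smooth_len && s$n_major[i] == s$n_major[i + 1] &&
            s$n_minor[i] == s$n_minor[i + 1]) {
          s$end[i] <- s$end[i + 1]
          s <- s[-(i + 1), , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    lens <- s$end - s$start + 1
    short <- which(lens < smooth_len)
    if (!length(short)) return(s)
    s <- s[-short[which.min(lens[short])], , drop = FALSE]
    if (nrow(s) == 0) return(s)
  }
}

# --- agreement-statistic oracles ---------------------------------------------

# ICC(3,1) via R's aov decomposition on the long data
oracle_icc3_aov <- function(x, y) {
  d <- data.frame(value = c(x, y),
                  subject = factor(rep(seq_along(x), 2)),
                  rater = factor(rep(1:2, each = length(x))))
  ms <- summary(stats::aov(value ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; mse <- ms[3]
  (msr - mse) / (msr + mse)
}

# Fleiss kappa from a 2x2 agreement table (a = both "1", b = rater1-only,
# c = rater2-only, d = both "0"), spreadsheet style
oracle_fleiss_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  p_obs <- (a + d) / n
  p1 <- (2 * a + b + c) / (2 * n)  # share of all ratings in category "1"
  pe <- p1^2 + (1 - p1)^2
  (p_obs - pe) / (1 - pe)
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign patterns
oracle_signed_rank_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  vs <- vapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:n]
    sum(r[signs == 1])
  }, numeric(1))
  mean(abs(vs - ev) >= abs(v_obs - ev))
}

# split one random segment of a profile into two pieces with identical state
random_split <- function(seg) {
  splittable <- which(seg$end > seg$start)
  if (!length(splittable)) return(seg)
  i <- if (length(splittable) == 1) splittable else sample(splittable, 1)
  cut <- seg$start[i] + sample(0:(seg$end[i] - seg$start[i] - 1), 1)
  left <- seg[i, ]; right <- seg[i, ]
  left$end <- cut; right$start <- cut + 1
  dplyr::bind_rows(seg[-i, ], left, right) |>
    dplyr::arrange(sample, chrom, start)
}
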