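#' Scoring parameters for the genomic-scar components
#'
#' Bundles the tunable constants of the three scar definitions. The defaults
#' are the published conventions: LOH regions must exceed 15 Mb (HRD-LOH),
#' large-scale state transitions require flanking segments of at least 10 Mb
#' after smoothing away segments under 3 Mb with an inter-flank gap of at
#' most 3 Mb (LST), telomeric allelic-imbalance segments have no minimum
#' length (NtAI), and the homologous-recombination status threshold is an
#' HRD score of 42 (ties classify as deficient).
#'
#' @param loh_min_len Minimum LOH-region length in bp, exclusive (`> 15 Mb`).
#' @param lst_min_flank Minimum flank length in bp for an LST (inclusive).
#' @param lst_smooth_len Segments shorter than this are removed before LST
#'   counting, and same-state neighbours separated by less than this are
#'   re-joined.
#' @param lst_max_gap Maximum genomic gap in bp between the two flanks of a
#'   counted transition.
#' @param ntai_min_len Minimum length in bp of a counted telomeric
#'   allelic-imbalance segment.
#' @param hr_threshold HRD score at or above which a sample is called HR
#'   deficient.
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(loh_min_len = 15e6, lst_min_flank = 10e6,
                           lst_smooth_len = 3e6, lst_max_gap = 3e6,
                           ntai_min_len = 0, hr_threshold = 42) {
  p <- list(loh_min_len = loh_min_len, lst_min_flank = lst_min_flank,
            lst_smooth_len = lst_smooth_len, lst_max_gap = lst_max_gap,
            ntai_min_len = ntai_min_len, hr_threshold = hr_threshold)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1 || v < 0, TRUE))) {
    stop("all scoring parameters must be single non-negative numbers", call. = FALSE)
  }
  if (p$hr_threshold <= 0) stop("hr_threshold must be positive", call. = FALSE)
  structure(p, class = "scoring_params")
}

#' Normalise a segment profile against a genome build
#'
#' Canonicalises a segment table so the scar scores see a well-defined
#' substrate: chromosomes absent from the build (sex chromosomes for the
#' bundled autosome-only GRCh37) are dropped; segments overlapping the
#' centromere are clipped to their p-arm and q-arm parts (bases inside the
#' centromere interval belong to neither arm and are removed); and runs of
#' gap-free adjacent segments with identical allele-specific state are merged
#' within each arm side. The operation is idempotent.
#'
#' @param seg Segment tibble (one or more samples).
#' @param build A `genome_build`.
#' @return Normalised segment tibble.
#' @export
normalize_profile <- function(seg, build) {
  seg <- validate_segments(seg)
  seg <- seg[seg$chrom %in% build$chromosomes$chrom, , drop = FALSE]
  if (nrow(seg) == 0) return(seg)
  len <- chrom_length(build, seg$chrom)
  if (any(seg$end > len)) {
    bad <- which(seg$end > len)[1]
    stop("segment beyond chromosome end: ", seg$chrom[bad], ":", seg$start[bad], "-",
         seg$end[bad], " (length ", len[bad], ")", call. = FALSE)
  }
  cen <- centromere_of(build, seg$chrom)
  p_part <- seg$start < cen$cen_start
  q_part <- seg$end > cen$cen_end
  p <- seg[p_part, , drop = FALSE]
  p$end <- pmin(p$end, cen$cen_start[p_part] - 1)
  q <- seg[q_part, , drop = FALSE]
  q$start <- pmax(q$start, cen$cen_end[q_part] + 1)
  out <- dplyr::arrange(rbind(p, q), .data$sample, .data$chrom, .data$start)
  merge_adjacent(out, max_gap = 0)
}

# Merge consecutive same-state segments per (sample, chrom); a pair merges
# when the gap between them is <= max_gap bp, or (heal_centromere) when the
# gap lies entirely inside the centromere interval. Extra columns are taken
# from the first segment of each run.
merge_adjacent <- function(seg, max_gap = 0, build = NULL, heal_centromere = FALSE) {
  if (nrow(seg) < 2) return(seg)
  n <- nrow(seg)
  prev <- seq_len(n - 1); nxt <- prev + 1
  same_chr <- seg$sample[nxt] == seg$sample[prev] & seg$chrom[nxt] == seg$chrom[prev]
  same_state <- seg$n_major[nxt] == seg$n_major[prev] & seg$n_minor[nxt] == seg$n_minor[prev]
  gap_start <- seg$end[prev] + 1
  gap_end <- seg$start[nxt] - 1
  ok_gap <- (gap_end - gap_start + 1) <= max_gap
  if (heal_centromere) {
    cen <- centromere_of(build, seg$chrom[prev])
    ok_gap <- ok_gap | (gap_start >= cen$cen_start & gap_end <= cen$cen_end)
  }
  joined <- same_chr & same_state & ok_gap
  run <- cumsum(c(TRUE, !joined))
  first <- !duplicated(run)
  out <- seg[first, , drop = FALSE]
  out$end <- vapply(split(seg$end, run), max, numeric(1), USE.NAMES = FALSE)
  out
}

seg_len <- function(seg) seg$end - seg$start + 1

# Per-sample view used by NtAI and HRD-LOH: the normalised profile with
# same-state runs re-joined across zero-length gaps and across gaps lying
# inside the centromere, so that a whole-chromosome event is a single
# centromere-crossing segment no matter how the caller (or normalisation)
# split it. Building on the normalised profile makes scoring invariant to
# whether the caller normalised first.
coalesced_view <- function(seg, build) {
  seg <- normalize_profile(seg, build)
  merge_adjacent(seg, max_gap = 0, build = build, heal_centromere = TRUE)
}

#' Count telomeric allelic-imbalance segments (NtAI)
#'
#' NtAI is the number of sub-chromosomal regions of allelic imbalance
#' (`n_major != n_minor`) extending to a telomere: per chromosome, the first
#' and last segments of the profile are candidates, and a candidate counts
#' when it does not cross the centromere, does not span the whole chromosome
#' (a single segment covering the entire profile of its chromosome), and is
#' at least `ntai_min_len` long. Terminality is profile-relative: real
#' allele-specific segmentations rarely reach literal base 1, so the first
#' (last) segment of a chromosome is taken to touch its telomere regardless
#' of a coordinate gap.
#'
#' @param seg Segment tibble (raw or normalised; same result either way).
#' @param build A `genome_build`.
#' @param params A [scoring_params()] list.
#' @return Tibble with columns `sample`, `ntai`.
#' @export
score_ntai <- function(seg, build, params = scoring_params()) {
  per_sample_counts(seg, build, params, ntai_one, "ntai")
}

#' Count long loss-of-heterozygosity regions (HRD-LOH)
#'
#' HRD-LOH is the number of LOH regions longer than `loh_min_len` (15 Mb by
#' default, exclusive) that do not span a whole chromosome. An LOH region is
#' a maximal run of segments with `n_minor = 0` and `n_major >= 1`, joined
#' across zero-length gaps and across the centromere irrespective of changes
#' in `n_major`; homozygous deletions (`0+0`) are not LOH (no allele is
#' retained) and terminate a run.
#'
#' @inheritParams score_ntai
#' @return Tibble with columns `sample`, `hrd_loh`.
#' @export
score_hrd_loh <- function(seg, build, params = scoring_params()) {
  per_sample_counts(seg, build, params, hrd_loh_one, "hrd_loh")
}

#' Count large-scale state transitions (LST)
#'
#' An LST is a breakpoint between two adjacent segments of different
#' allele-specific state, each at least `lst_min_flank` (10 Mb) long, with a
#' genomic gap of at most `lst_max_gap` (3 Mb) between them. Counting is per
#' chromosome arm on the normalised profile after smoothing: segments shorter
#' than `lst_smooth_len` (3 Mb) are iteratively removed (shortest first) and
#' same-state neighbours separated by less than `lst_smooth_len` re-joined,
#' until stable.
#'
#' @inheritParams score_ntai
#' @return Tibble with columns `sample`, `lst`.
#' @export
score_lst <- function(seg, build, params = scoring_params()) {
  per_sample_counts(seg, build, params, lst_one, "lst")
}

per_sample_counts <- function(seg, build, params, fun, col) {
  seg <- validate_segments(seg)
  samples <- unique(seg$sample)
  counts <- vapply(samples, function(s) {
    fun(seg[seg$sample == s, , drop = FALSE], build, params)
  }, numeric(1))
  out <- tibble::tibble(sample = samples, value = as.integer(counts))
  names(out)[2] <- col
  out
}

ntai_one <- function(seg, build, params) {
  v <- coalesced_view(seg, build)
  if (nrow(v) == 0) return(0L)
  total <- 0L
  for (ch in unique(v$chrom)) {
    s <- v[v$chrom == ch, , drop = FALSE]
    n <- nrow(s)
    idx <- unique(c(1L, n))
    for (i in idx) {
      if (s$n_major[i] == s$n_minor[i]) next
      if (n == 1L) next  # single segment spans the whole chromosome profile
      if (crosses_centromere(build, s$chrom[i], s$start[i], s$end[i])) next
      if (seg_len(s[i, ]) < params$ntai_min_len) next
      total <- total + 1L
    }
  }
  total
}

hrd_loh_one <- function(seg, build, params) {
  v <- coalesced_view(seg, build)
  if (nrow(v) == 0) return(0L)
  total <- 0L
  for (ch in unique(v$chrom)) {
    s <- v[v$chrom == ch, , drop = FALSE]
    is_loh <- s$n_minor == 0 & s$n_major >= 1
    if (!any(is_loh)) next
    n <- nrow(s)
    # join consecutive LOH segments across zero gaps / the centromere,
    # irrespective of n_major
    joined <- rep(FALSE, max(n - 1, 0))
    if (n > 1) {
      prev <- seq_len(n - 1); nxt <- prev + 1
      gap_start <- s$end[prev] + 1; gap_end <- s$start[nxt] - 1
      cen <- centromere_of(build, s$chrom[prev])
      ok_gap <- (gap_end - gap_start + 1) <= 0 |
        (gap_start >= cen$cen_start & gap_end <= cen$cen_end)
      joined <- is_loh[prev] & is_loh[nxt] & ok_gap
    }
    run <- cumsum(c(TRUE, !joined))
    for (r in unique(run[is_loh])) {
      idx <- which(run == r & is_loh)
      reg_start <- s$start[idx[1]]; reg_end <- s$end[idx[length(idx)]]
      whole <- idx[1] == 1L && idx[length(idx)] == n
      if (!whole && (reg_end - reg_start + 1) > params$loh_min_len) total <- total + 1L
    }
  }
  total
}

lst_one <- function(seg, build, params) {
  norm <- normalize_profile(seg, build)
  if (nrow(norm) == 0) return(0L)
  norm$arm <- arm_of(build, norm$chrom, norm$start, norm$end)
  total <- 0L
  for (key in unique(paste(norm$chrom, norm$arm))) {
    s <- norm[paste(norm$chrom, norm$arm) == key, , drop = FALSE]
    s <- smooth_arm(s, params$lst_smooth_len)
    n <- nrow(s)
    if (n < 2) next
    prev <- seq_len(n - 1); nxt <- prev + 1
    diff_state <- s$n_major[prev] != s$n_major[nxt] | s$n_minor[prev] != s$n_minor[nxt]
    flanks_ok <- seg_len(s)[prev] >= params$lst_min_flank &
      seg_len(s)[nxt] >= params$lst_min_flank
    gap_ok <- (s$start[nxt] - s$end[prev] - 1) <= params$lst_max_gap
    total <- total + sum(diff_state & flanks_ok & gap_ok)
  }
  as.integer(total)
}

# Iterative small-segment removal on one arm: drop the shortest segment under
# `smooth_len`, re-join same-state neighbours separated by < smooth_len,
# repeat until no segment is below the threshold.
smooth_arm <- function(s, smooth_len) {
  repeat {
    s <- merge_adjacent(s, max_gap = smooth_len - 1)
    lens <- seg_len(s)
    short <- which(lens < smooth_len)
    if (length(short) == 0) return(s)
    drop <- short[which.min(lens[short])]
    s <- s[-drop, , drop = FALSE]
    if (nrow(s) == 0) return(s)
  }
}

#' Classify homologous-recombination status from an HRD score
#'
#' Deficient iff `score >= threshold`; ties go to deficient, per the
#' standard `>= 42` rule.
#'
#' @param score Numeric vector of HRD scores.
#' @param threshold Classification threshold (default 42).
#' @return Character vector of `"deficient"` / `"proficient"`.
#' @examples
#' classify_hr(c(43, 41, 42, 0))
#' @export
classify_hr <- function(score, threshold = 42) {
  stopifnot(all(score >= 0))
  ifelse(score >= threshold, "deficient", "proficient")
}

#' Compute the HRD score and its components for each sample
#'
#' Runs [score_ntai()], [score_hrd_loh()] and [score_lst()], sums the three
#' counts into the HRD score, classifies HR status at `params$hr_threshold`,
#' and reports each component's percentage contribution to the score (all
#' zero for a score of 0).
#'
#' @inheritParams score_ntai
#' @return Tibble with columns `sample`, `ntai`, `hrd_loh`, `lst`,
#'   `hrd_score`, `hr_status`, `pct_ntai`, `pct_hrd_loh`, `pct_lst`.
#' @examples
#' build <- load_build("GRCh37")
#' seg <- tibble::tibble(sample = "S1", chrom = "1",
#'                       start = c(1, 30e6), end = c(30e6 - 1, 120e6),
#'                       n_major = c(2, 1), n_minor = c(1, 1))
#' score_hrd(seg, build)
#' @export
score_hrd <- function(seg, build, params = scoring_params()) {
  res <- score_ntai(seg, build, params) |>
    dplyr::left_join(score_hrd_loh(seg, build, params), by = "sample") |>
    dplyr::left_join(score_lst(seg, build, params), by = "sample") |>
    dplyr::mutate(
      hrd_score = .data$ntai + .data$hrd_loh + .data$lst,
      hr_status = classify_hr(.data$hrd_score, params$hr_threshold),
      pct_ntai = ifelse(.data$hrd_score > 0, 100 * .data$ntai / .data$hrd_score, 0),
      pct_hrd_loh = ifelse(.data$hrd_score > 0, 100 * .data$hrd_loh / .data$hrd_score, 0),
      pct_lst = ifelse(.data$hrd_score > 0, 100 * .data$lst / .data$hrd_score, 0)
    )
  res
}
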