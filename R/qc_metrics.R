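#' Derivative Log Ratio Spread (dLRS)
#'
#' Probe-to-probe noise of a Log2-ratio track: the sample standard deviation
#' of first differences between genomically adjacent probes, divided by
#' sqrt(2) so that for white noise it estimates the per-probe standard
#' deviation. Differences are taken within chromosomes only — never across a
#' chromosome boundary. `plain_sd = TRUE` instead returns the plain standard
#' deviation of the Log2 ratios themselves (no differencing).
#'
#' @param track Probe-track tibble (`chrom`, `pos`, `log2`).
#' @param plain_sd Use the plain (non-derivative) standard deviation.
#' @return A single non-negative number.
#' @export
dlrs <- function(track, plain_sd = FALSE) {
  track <- validate_probe_track(track)
  if (nrow(track) < 3) stop("dLRS needs at least 3 probes", call. = FALSE)
  if (plain_sd) return(stats::sd(track$log2))
  d <- adjacent_diffs(track)
  if (length(d) < 2) stop("dLRS needs at least 2 within-chromosome adjacent differences", call. = FALSE)
  stats::sd(d) / sqrt(2)
}

#' Median of Absolute Pairwise Differences (MAPD)
#'
#' The median of `|Log2[i+1] - Log2[i]|` over genomically adjacent probe
#' pairs within chromosomes. A robust counterpart of [dlrs()].
#'
#' @inheritParams dlrs
#' @return A single non-negative number.
#' @export
mapd <- function(track) {
  track <- validate_probe_track(track)
  d <- adjacent_diffs(track)
  if (length(d) < 1) stop("MAPD needs at least 2 probes on one chromosome", call. = FALSE)
  stats::median(abs(d))
}

adjacent_diffs <- function(track) {
  unlist(lapply(split(track$log2, track$chrom), diff), use.names = FALSE)
}

#' Median Log2 ratio per fixed-width genomic bin
#'
#' Maps Log2-ratio data onto a bin grid (10 kb by default elsewhere) and
#' takes the per-bin median, the common ground on which array- and
#' WGS-derived tracks can be compared even when their probe positions differ.
#'
#' Two modes:
#' * `mode = "probe"`: `x` is a probe track; each probe contributes its
#'   `log2` value to the bin containing its position.
#' * `mode = "segmented"`: `x` is a segment table (one sample); each segment
#'   contributes one Log2 value to every bin it overlaps (not
#'   length-weighted). The segment value is taken from a `log2` column when
#'   present, otherwise computed as `log2(max(n_major + n_minor, 0.5) /
#'   ploidy)` with ploidy from the table's `ploidy` column or the `ploidy`
#'   argument.
#'
#' Bins with no mapped data are `NA`.
#'
#' @param x Probe track or segment tibble.
#' @param grid A `bin_grid` from [make_bins()].
#' @param mode `"probe"` or `"segmented"`.
#' @param ploidy Fallback sample ploidy for segmented mode (default 2).
#' @return A binned track: tibble over the full grid with columns `chrom`,
#'   `bin`, `start`, `end`, `value`.
#' @export
bin_median <- function(x, grid, mode = c("probe", "segmented"), ploidy = 2) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "bin_grid"))
  if (mode == "probe") {
    x <- validate_probe_track(x)
    mapped <- tibble::tibble(bin = bin_index(grid, x$chrom, x$pos), value = x$log2)
  } else {
    x <- validate_segments(if (!"sample" %in% names(x)) dplyr::mutate(x, sample = "s") else x)
    if (length(unique(x$sample)) > 1) stop("segmented mode takes one sample at a time", call. = FALSE)
    if (!"log2" %in% names(x)) {
      pl <- if ("ploidy" %in% names(x)) x$ploidy else ploidy
      x$log2 <- log2(pmax(x$n_major + x$n_minor, 0.5) / pl)
    }
    b0 <- bin_index(grid, x$chrom, x$start)
    b1 <- bin_index(grid, x$chrom, x$end)
    mapped <- tibble::tibble(
      bin = unlist(purrr::map2(b0, b1, seq), use.names = FALSE),
      value = rep(x$log2, b1 - b0 + 1)
    )
  }
  med <- mapped |>
    dplyr::summarise(value = stats::median(.data$value), .by = "bin")
  out <- grid$bins
  out$value <- med$value[match(out$bin, med$bin)]
  out
}

joint_bins <- function(a, b) {
  if (nrow(a) != nrow(b) || !all(a$bin == b$bin)) {
    stop("binned tracks are on different grids", call. = FALSE)
  }
  ok <- !is.na(a$value) & !is.na(b$value)
  list(a = a$value[ok], b = b$value[ok])
}

#' Median absolute deviation between two binned Log2 tracks
#'
#' The median of `|a - b|` over bins where both tracks have data; the
#' cross-platform "deviation in segmented Log2 ratio" metric.
#'
#' @param a,b Binned tracks from [bin_median()] on the same grid.
#' @return A single non-negative number.
#' @export
binned_deviation <- function(a, b) {
  j <- joint_bins(a, b)
  if (length(j$a) == 0) stop("no jointly covered bins", call. = FALSE)
  stats::median(abs(j$a - j$b))
}

#' Spearman correlation between two binned Log2 tracks
#'
#' Rank correlation over jointly covered bins. Returns `NA` with a warning
#' when either track is constant over the joint bins (the correlation is
#' undefined there).
#'
#' @inheritParams binned_deviation
#' @return A number in \[-1, 1\], or `NA`.
#' @export
binned_spearman <- function(a, b) {
  j <- joint_bins(a, b)
  if (length(j$a) < 3) stop("Spearman correlation needs at least 3 jointly covered bins", call. = FALSE)
  if (stats::sd(j$a) == 0 || stats::sd(j$b) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(j$a, j$b, method = "spearman")
}
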