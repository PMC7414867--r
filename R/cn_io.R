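#' Read an allele-specific copy-number segmentation table
#'
#' Consumes the per-segment output of allele-specific copy-number callers
#' (ASCAT for arrays, ascatNgs for WGS) as a tidy segment table. Three
#' dialects are understood:
#'
#' * `"generic"`: TSV with header `sample chrom start end nMajor nMinor`;
#' * `"ascat"`: TSV with header `sample chr startpos endpos nMajor nMinor`;
#' * `"ascatngs"`: the `*.copynumber.caveman.csv` layout — headerless CSV with
#'   columns id, chrom, start, end, normal total, normal minor, tumour total,
#'   tumour minor; major/minor tumour allele counts are derived as
#'   `tumour_total - tumour_minor` and `tumour_minor`.
#'
#' Coordinates are 1-based and fully closed throughout. Rows with
#' `n_minor > n_major` are canonicalised by swapping the two (with a warning):
#' allele-specific callers label alleles arbitrarily. Adjacent rows with the
#' same copy-number state are kept as given; merging is an explicit
#' normalisation step (see [normalize_profile()]). Gaps between consecutive
#' segments are permitted (centromeres, unsegmentable regions). Non-integer
#' copy numbers (subclonal estimates) are rejected unless `round_cn = TRUE`,
#' which rounds half away from zero: the scar definitions are stated on
#' integer allele counts.
#'
#' @param path File path.
#' @param dialect One of `"generic"`, `"ascat"`, `"ascatngs"`.
#' @param sample_id Sample label for dialects whose files carry none
#'   (`"ascatngs"`); defaults to the file name stem.
#' @param purity,ploidy Optional sample metadata (aberrant cell fraction in
#'   (0, 1]; ploidy > 0), attached as columns.
#' @param round_cn Round non-integer copy numbers instead of erroring.
#' @return A tibble with columns `sample`, `chrom`, `start`, `end`,
#'   `n_major`, `n_minor` (plus `purity`/`ploidy` when supplied), sorted by
#'   `(sample, chrom, start)` and validated.
#' @export
read_segments <- function(path, dialect = c("generic", "ascat", "ascatngs"),
                          sample_id = NULL, purity = NULL, ploidy = NULL,
                          round_cn = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  seg <- switch(
    dialect,
    generic = {
      x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()))
      need <- c("sample", "chrom", "start", "end", "nMajor", "nMinor")
      if (!all(need %in% names(x))) {
        stop("generic dialect needs columns: ", paste(setdiff(need, names(x)), collapse = ", "),
             call. = FALSE)
      }
      tibble::tibble(sample = as.character(x$sample), chrom = canonical_chrom(x$chrom),
                     start = x$start, end = x$end,
                     n_major = x$nMajor, n_minor = x$nMinor)
    },
    ascat = {
      x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()))
      need <- c("sample", "chr", "startpos", "endpos", "nMajor", "nMinor")
      if (!all(need %in% names(x))) {
        stop("ascat dialect needs columns: ", paste(setdiff(need, names(x)), collapse = ", "),
             call. = FALSE)
      }
      tibble::tibble(sample = as.character(x$sample), chrom = canonical_chrom(x$chr),
                     start = x$startpos, end = x$endpos,
                     n_major = x$nMajor, n_minor = x$nMinor)
    },
    ascatngs = {
      x <- utils::read.csv(path, header = FALSE)
      if (ncol(x) < 8) stop("ascatngs dialect expects 8 headerless CSV columns", call. = FALSE)
      names(x)[1:8] <- c("id", "chrom", "start", "end",
                         "normal_total", "normal_minor", "tumour_total", "tumour_minor")
      sid <- sample_id %||% sub("\\..*$", "", basename(path))
      tibble::tibble(sample = sid, chrom = canonical_chrom(x$chrom),
                     start = x$start, end = x$end,
                     n_major = x$tumour_total - x$tumour_minor,
                     n_minor = x$tumour_minor)
    }
  )
  if (!is.null(sample_id) && dialect != "ascatngs") seg$sample <- sample_id
  if (!is.null(purity)) {
    stopifnot(purity > 0, purity <= 1)
    seg$purity <- purity
  }
  if (!is.null(ploidy)) {
    stopifnot(ploidy > 0)
    seg$ploidy <- ploidy
  }
  validate_segments(seg, round_cn = round_cn)
}

#' Validate (and canonicalise) a segment table
#'
#' Checks the segment-table contract: `start <= end`, non-negative integer
#' allele counts, per-sample-per-chromosome sorting and no overlaps. Rows with
#' `n_minor > n_major` are swapped with a warning.
#'
#' @param seg Tibble with columns `sample`, `chrom`, `start`, `end`,
#'   `n_major`, `n_minor`.
#' @param round_cn Round non-integer copy numbers half away from zero instead
#'   of erroring.
#' @return The validated tibble, sorted by `(sample, chrom, start)`.
#' @export
validate_segments <- function(seg, round_cn = FALSE) {
  need <- c("sample", "chrom", "start", "end", "n_major", "n_minor")
  miss <- setdiff(need, names(seg))
  if (length(miss)) stop("segment table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  seg <- tibble::as_tibble(seg)
  seg$chrom <- canonical_chrom(seg$chrom)
  if (anyNA(seg[need])) stop("missing values in segment table", call. = FALSE)
  bad <- which(seg$start > seg$end)
  if (length(bad)) stop("start > end at row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  nonint <- which(seg$n_major != round(seg$n_major) | seg$n_minor != round(seg$n_minor))
  if (length(nonint)) {
    if (!round_cn) {
      stop("non-integer copy numbers at row(s) ", paste(utils::head(nonint, 5), collapse = ", "),
           "; use round_cn = TRUE for subclonal estimates", call. = FALSE)
    }
    seg$n_major <- sign(seg$n_major) * floor(abs(seg$n_major) + 0.5)
    seg$n_minor <- sign(seg$n_minor) * floor(abs(seg$n_minor) + 0.5)
  }
  bad <- which(seg$n_major < 0 | seg$n_minor < 0)
  if (length(bad)) stop("negative copy number at row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  swap <- seg$n_minor > seg$n_major
  if (any(swap)) {
    warning(sum(swap), " row(s) with n_minor > n_major; swapping to the major/minor convention")
    tmp <- seg$n_major[swap]
    seg$n_major[swap] <- seg$n_minor[swap]
    seg$n_minor[swap] <- tmp
  }
  ord <- order(seg$sample, seg$chrom, seg$start)
  seg_row <- seq_len(nrow(seg))[ord]
  seg <- seg[ord, ]
  same <- nrow(seg) > 1 &
    seg$sample[-1] == seg$sample[-nrow(seg)] & seg$chrom[-1] == seg$chrom[-nrow(seg)]
  overlap <- which(same & seg$start[-1] <= seg$end[-nrow(seg)])
  if (length(overlap)) {
    i <- overlap[1]
    stop("overlapping segments: input rows ", seg_row[i], " and ", seg_row[i + 1],
         " (", seg$chrom[i], ":", seg$start[i], "-", seg$end[i], " vs ",
         seg$start[i + 1], "-", seg$end[i + 1], ")", call. = FALSE)
  }
  seg
}

#' Read a probe-level Log2-ratio (and optional BAF) track
#'
#' TSV with header `chrom pos log2` and an optional `baf` column; positions
#' must be strictly increasing within a chromosome and BAF values must lie in
#' \[0, 1\]. Optionally carries a `sample` column.
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `pos`, `log2` (+ `baf`, `sample`),
#'   sorted by `(chrom, pos)`.
#' @export
read_probe_track <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()))
  need <- c("chrom", "pos", "log2")
  if (!all(need %in% names(x))) {
    stop("probe track needs columns: ", paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  x$chrom <- canonical_chrom(x$chrom)
  validate_probe_track(tibble::as_tibble(x))
}

validate_probe_track <- function(track) {
  track <- dplyr::arrange(track, .data$chrom, .data$pos)
  dup <- track |>
    dplyr::summarise(bad = anyDuplicated(.data$pos) > 0, .by = "chrom")
  if (any(dup$bad)) {
    stop("duplicated probe position on chromosome(s): ",
         paste(dup$chrom[dup$bad], collapse = ", "), call. = FALSE)
  }
  if ("baf" %in% names(track)) {
    ok <- is.na(track$baf) | (track$baf >= 0 & track$baf <= 1)
    if (!all(ok)) stop("baf outside [0, 1]", call. = FALSE)
  }
  track
}

#' Write scoring or agreement results to disk
#'
#' HRD result tables are written as TSV (deterministic column order) or JSON;
#' agreement reports as JSON (their natural nested shape) or a flat TSV
#' summary of the per-metric statistics. Numeric fields are written at full
#' precision so a write-read roundtrip is the identity.
#'
#' @param results A tibble of HRD results (as from [score_hrd()]) or an
#'   `agreement_report` (as from [build_agreement_report()]).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (is.null(results) || (is.data.frame(results) && nrow(results) == 0)) {
    stop("empty results", call. = FALSE)
  }
  if (inherits(results, "agreement_report")) {
    if (format == "json") {
      serialisable <- unclass(results)
      serialisable$bland_altman <- lapply(results$bland_altman,
                                          function(b) unclass(b))
      jsonlite::write_json(serialisable, path, auto_unbox = TRUE, digits = NA, null = "null")
    } else {
      readr::write_tsv(tidy.agreement_report(results), path)
    }
  } else if (is.data.frame(results)) {
    if (format == "json") {
      jsonlite::write_json(results, path, auto_unbox = FALSE, digits = NA)
    } else {
      readr::write_tsv(results, path)
    }
  } else {
    stop("unsupported results object of class ", paste(class(results), collapse = "/"), call. = FALSE)
  }
  invisible(path)
}

#' Write a segment table in the generic TSV dialect
#'
#' @param seg Segment tibble (`sample`, `chrom`, `start`, `end`, `n_major`,
#'   `n_minor`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(seg, path) {
  out <- tibble::tibble(sample = seg$sample, chrom = seg$chrom,
                        start = seg$start, end = seg$end,
                        nMajor = seg$n_major, nMinor = seg$n_minor)
  readr::write_tsv(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
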