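#' Load a genome build (chromosome lengths and centromere intervals)
#'
#' A genome build defines the coordinate system every other computation in
#' this package works in: chromosome lengths, one centromere interval per
#' chromosome (which splits it into a p and a q arm), and hence the telomere,
#' arm and bin logic used by the scar scores and the 10 kb binning.
#'
#' The bundled `"GRCh37"` build carries the 22 autosomes of GRCh37/hg19 with
#' centromere intervals taken from the UCSC gap table, collapsed to a single
#' interval per chromosome and converted to 1-based fully-closed coordinates.
#' Sex chromosomes are deliberately absent: scar scoring is defined on
#' autosomes 1-22.
#'
#' Custom builds are loaded from two plain TSV files: a lengths table with
#' header `chrom  length` and a centromere table with header
#' `chrom  cen_start  cen_end` (1-based, closed). Chromosome names may carry
#' or omit a `"chr"` prefix; it is stripped internally.
#'
#' @param name Build label. `"GRCh37"` loads the bundled build; any other
#'   value must be accompanied by `lengths_file` and `centromeres_file`.
#' @param lengths_file,centromeres_file Paths to the two TSV tables for a
#'   custom build.
#' @return An object of class `genome_build`: a list with `name`,
#'   `chromosomes` (tibble `chrom`, `length`) and `centromeres` (tibble
#'   `chrom`, `cen_start`, `cen_end`), chromosomes in file order.
#' @examples
#' build <- load_build("GRCh37")
#' build$chromosomes
#' @export
load_build <- function(name = "GRCh37", lengths_file = NULL, centromeres_file = NULL) {
  if (is.null(lengths_file) != is.null(centromeres_file)) {
    stop("supply both `lengths_file` and `centromeres_file`, or neither", call. = FALSE)
  }
  if (is.null(lengths_file)) {
    if (!identical(toupper(name), "GRCH37")) {
      stop("unknown build label '", name, "'; bundled builds: GRCh37", call. = FALSE)
    }
    lengths_file <- system.file("extdata", "grch37_lengths.tsv", package = "hrdscar", mustWork = TRUE)
    centromeres_file <- system.file("extdata", "grch37_centromeres.tsv", package = "hrdscar", mustWork = TRUE)
    name <- "GRCh37"
  }
  lens <- readr::read_tsv(lengths_file, col_types = readr::cols(
    chrom = readr::col_character(), length = readr::col_double()
  ))
  cens <- readr::read_tsv(centromeres_file, col_types = readr::cols(
    chrom = readr::col_character(), cen_start = readr::col_double(), cen_end = readr::col_double()
  ))
  if (!all(c("chrom", "length") %in% names(lens)) ||
      !all(c("chrom", "cen_start", "cen_end") %in% names(cens))) {
    stop("malformed build tables: expected headers `chrom length` and `chrom cen_start cen_end`", call. = FALSE)
  }
  lens$chrom <- canonical_chrom(lens$chrom)
  cens$chrom <- canonical_chrom(cens$chrom)
  if (anyDuplicated(lens$chrom)) stop("duplicate chromosome names in lengths table", call. = FALSE)
  if (any(lens$length <= 0)) stop("non-positive chromosome length", call. = FALSE)
  missing_cen <- setdiff(lens$chrom, cens$chrom)
  if (length(missing_cen)) {
    stop("no centromere interval for chromosome(s): ", paste(missing_cen, collapse = ", "), call. = FALSE)
  }
  cens <- dplyr::left_join(lens, cens, by = "chrom")
  bad <- cens$cen_start <= 1 | cens$cen_end <= cens$cen_start | cens$cen_end >= cens$length
  if (any(bad)) {
    stop("centromere interval outside chromosome for: ",
         paste(cens$chrom[bad], collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      name = name,
      chromosomes = tibble::as_tibble(lens),
      centromeres = tibble::as_tibble(cens[, c("chrom", "cen_start", "cen_end")])
    ),
    class = "genome_build"
  )
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build> ", x$name, ": ", nrow(x$chromosomes), " chromosomes, ",
      format(sum(x$chromosomes$length), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Construct a genome build from in-memory tables
#'
#' Mostly useful for toy genomes in examples and simulations. Same validation
#' as [load_build()].
#'
#' @param chromosomes Tibble/data frame with columns `chrom`, `length`.
#' @param centromeres Tibble/data frame with columns `chrom`, `cen_start`,
#'   `cen_end` (1-based, closed).
#' @param name Build label.
#' @return A `genome_build`.
#' @export
genome_build <- function(chromosomes, centromeres, name = "custom") {
  lf <- tempfile(fileext = ".tsv"); cf <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(lf, cf)))
  readr::write_tsv(chromosomes, lf)
  readr::write_tsv(centromeres, cf)
  load_build(name, lengths_file = lf, centromeres_file = cf)
}

canonical_chrom <- function(x) sub("^chr", "", as.character(x))

chrom_length <- function(build, chrom) {
  i <- match(canonical_chrom(chrom), build$chromosomes$chrom)
  if (anyNA(i)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  build$chromosomes$length[i]
}

centromere_of <- function(build, chrom) {
  i <- match(canonical_chrom(chrom), build$centromeres$chrom)
  if (anyNA(i)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  build$centromeres[i, ]
}

#' Tile a genome build with fixed-width bins
#'
#' Each chromosome is tiled left to right with consecutive, non-overlapping
#' bins of `bin_size` bp; the final bin of a chromosome may be partial, so the
#' per-chromosome bin count is `ceiling(length / bin_size)`. At the default
#' 10 kb this yields exactly 288,113 bins over the GRCh37 autosomes.
#'
#' @param build A `genome_build`.
#' @param bin_size Bin width in bp (default 10,000).
#' @return An object of class `bin_grid`: list with `bin_size`, `bins`
#'   (tibble `chrom`, `bin` global index, `start`, `end`), `per_chrom`
#'   (tibble `chrom`, `n_bins`, `offset`) and `total`.
#' @examples
#' grid <- make_bins(load_build("GRCh37"), 10000)
#' grid$total
#' @export
make_bins <- function(build, bin_size = 10000) {
  stopifnot(inherits(build, "genome_build"))
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0) {
    stop("`bin_size` must be a single positive number", call. = FALSE)
  }
  per <- build$chromosomes |>
    dplyr::mutate(n_bins = ceiling(.data$length / bin_size)) |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$n_bins, default = 0)))
  bins <- per |>
    dplyr::reframe(
      bin = .data$offset + seq_len(.data$n_bins),
      start = (seq_len(.data$n_bins) - 1) * bin_size + 1,
      end = pmin(seq_len(.data$n_bins) * bin_size, .data$length),
      .by = "chrom"
    )
  structure(
    list(
      bin_size = bin_size,
      bins = tibble::as_tibble(bins),
      per_chrom = per[, c("chrom", "n_bins", "offset")],
      total = sum(per$n_bins)
    ),
    class = "bin_grid"
  )
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("<bin_grid> ", format(x$total, big.mark = ","), " bins of ",
      format(x$bin_size, big.mark = ","), " bp over ",
      nrow(x$per_chrom), " chromosomes\n", sep = "")
  invisible(x)
}

#' Map genomic positions to global bin indices
#'
#' @param grid A `bin_grid`.
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @return Integer vector of global bin indices (1..`grid$total`).
#' @export
bin_index <- function(grid, chrom, pos) {
  stopifnot(inherits(grid, "bin_grid"))
  chrom <- canonical_chrom(chrom)
  i <- match(chrom, grid$per_chrom$chrom)
  if (anyNA(i)) {
    stop("chromosome absent from grid: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  local <- ceiling(pos / grid$bin_size)
  bad <- pos < 1 | local > grid$per_chrom$n_bins[i]
  if (any(bad)) stop("position out of chromosome bounds", call. = FALSE)
  as.integer(grid$per_chrom$offset[i] + local)
}

#' Does an interval have bases on both sides of the centromere?
#'
#' True iff the closed interval `[start, end]` contains at least one position
#' strictly below the centromere start and at least one strictly above the
#' centromere end. An interval that merely ends (or starts) inside the
#' centromere interval does not cross it.
#'
#' @param build A `genome_build`.
#' @param chrom,start,end Vectors describing intervals (1-based, closed).
#' @return Logical vector.
#' @export
crosses_centromere <- function(build, chrom, start, end) {
  check_intervals(build, chrom, start, end)
  cen <- centromere_of(build, chrom)
  start < cen$cen_start & end > cen$cen_end
}

#' Chromosome-arm label of an interval
#'
#' `"p"` if the interval lies entirely before the centromere start, `"q"` if
#' entirely after the centromere end, otherwise `"spanning"`. Positions inside
#' the centromere interval belong to neither arm, so an interval ending inside
#' it is already `"spanning"`.
#'
#' @inheritParams crosses_centromere
#' @return Character vector of `"p"`, `"q"`, `"spanning"`.
#' @export
arm_of <- function(build, chrom, start, end) {
  check_intervals(build, chrom, start, end)
  cen <- centromere_of(build, chrom)
  dplyr::case_when(
    end < cen$cen_start ~ "p",
    start > cen$cen_end ~ "q",
    .default = "spanning"
  )
}

check_intervals <- function(build, chrom, start, end) {
  len <- chrom_length(build, chrom)
  if (any(start > end)) stop("interval with start > end", call. = FALSE)
  if (any(start < 1 | end > len)) stop("interval out of chromosome bounds", call. = FALSE)
  invisible(TRUE)
}
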