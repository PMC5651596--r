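#' Construct a genetic map
#'
#' A genetic map is a monotone mapping from physical position (bp) to
#' cumulative genetic distance (cM), stored as marker positions with their
#' cumulative cM per chromosome. It is the rate oracle behind every
#' recombination-rate computation: the rate of an interval is the cM
#' accumulated across it divided by its physical length in Mb.
#'
#' @param x Data frame with columns `chrom`, `pos` (bp, 0-based), `cum_cm`.
#' @return A tibble classed `genetic_map`.
#' @examples
#' genetic_map(tibble::tibble(
#'   chrom = "chr1", pos = c(1000, 2000, 4000), cum_cm = c(0, 0.01, 0.05)
#' ))
#' @export
genetic_map <- function(x) {
  x <- as_tibble(x)[c("chrom", "pos", "cum_cm")]
  x <- dplyr::arrange(x, .data$chrom, .data$pos)
  for (cn in unique(x$chrom)) {
    d <- x[x$chrom == cn, ]
    if (nrow(d) < 2) abort(paste0("chromosome ", cn, " has < 2 markers"))
    dp <- diff(d$pos)
    if (any(dp <= 0)) {
      abort(paste0("non-monotone marker positions on ", cn,
                   " at row ", which(dp <= 0)[1] + 1L))
    }
    dc <- diff(d$cum_cm)
    if (any(dc < 0)) {
      abort(paste0("decreasing cumulative cM on ", cn,
                   " at row ", which(dc < 0)[1] + 1L))
    }
  }
  new_tibble_class(x, "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map> ", length(unique(x$chrom)), " chromosome(s), ",
      format(nrow(x), big.mark = ","), " markers, ",
      round(sum(tapply(x$cum_cm, x$chrom, function(v) max(v) - min(v))), 2),
      " cM total\n", sep = "")
  NextMethod()
}

#' Read a genetic map from text
#'
#' Supports the common map dialects:
#' * `pos_rate_cm` — 3 columns: position, rate (cM/Mb), cumulative cM
#'   (HapMap-style); the cumulative column is used directly.
#' * `pos_cm` — 2 columns: position, cumulative cM.
#' * `pos_rate` — 2 columns: position, rate (cM/Mb); cumulative cM is
#'   reconstructed by integrating the piecewise-constant rate between
#'   consecutive markers (the last rate extends nowhere and is unused).
#'
#' Files may carry a `chrom` first column; single-chromosome files take the
#' chromosome from `chrom`. Positions in map files are conventionally
#' 1-based; set `coords = "one"` (default) to convert to the internal
#' 0-based convention, `"zero"` to take them as-is.
#'
#' @param path Path (optionally gzipped); tab- or space-separated, optional
#'   header line starting with a non-numeric token.
#' @param dialect One of `"pos_rate_cm"`, `"pos_cm"`, `"pos_rate"`.
#' @param chrom Chromosome name used when the file has no chrom column.
#' @param coords `"one"` or `"zero"` basis of file positions.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path, dialect = c("pos_rate_cm", "pos_cm", "pos_rate"),
                             chrom = "chr1", coords = c("one", "zero")) {
  dialect <- match.arg(dialect)
  coords <- match.arg(coords)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_table(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE, comment = "#")
  # drop a header row if the position column is non-numeric
  if (nrow(raw) > 0 && is.na(suppressWarnings(as.numeric(raw[[ncol(raw)]][1])))) {
    raw <- raw[-1, ]
  }
  has_chrom <- is.na(suppressWarnings(as.numeric(raw[[1]][1])))
  ncol_needed <- switch(dialect, pos_rate_cm = 3L, pos_cm = 2L, pos_rate = 2L)
  if (ncol(raw) < ncol_needed + has_chrom) {
    abort(paste0("dialect ", dialect, " needs ", ncol_needed,
                 " data columns; file has ", ncol(raw) - has_chrom))
  }
  cn <- if (has_chrom) as.character(raw[[1]]) else rep(chrom, nrow(raw))
  off <- as.integer(has_chrom)
  pos <- as.numeric(raw[[off + 1L]])
  if (anyNA(pos)) abort(paste0("non-numeric position at row ", which(is.na(pos))[1]))
  if (coords == "one") pos <- pos - 1
  out <- switch(dialect,
    pos_rate_cm = tibble(chrom = cn, pos = pos, cum_cm = as.numeric(raw[[off + 3L]])),
    pos_cm = tibble(chrom = cn, pos = pos, cum_cm = as.numeric(raw[[off + 2L]])),
    pos_rate = {
      rate <- as.numeric(raw[[off + 2L]])
      if (any(rate < 0, na.rm = TRUE)) {
        abort(paste0("negative rate at row ", which(rate < 0)[1]))
      }
      d <- tibble(chrom = cn, pos = pos, rate = rate) |>
        dplyr::group_by(.data$chrom) |>
        dplyr::arrange(.data$pos, .by_group = TRUE) |>
        dplyr::mutate(cum_cm = cumsum(dplyr::lag(.data$rate, default = 0) *
                                        c(0, diff(.data$pos)) / 1e6)) |>
        dplyr::ungroup()
      d[c("chrom", "pos", "cum_cm")]
    })
  # surface a decreasing-cM row with its file row number before construction
  for (one_chrom in unique(out$chrom)) {
    cc <- out$cum_cm[out$chrom == one_chrom]
    bad <- which(diff(cc) < 0)
    if (length(bad) > 0) {
      row_in_file <- which(out$chrom == one_chrom)[bad[1] + 1L]
      abort(paste0("cumulative cM decreases at row ", row_in_file, " (", one_chrom, ")"))
    }
  }
  genetic_map(out)
}

map_chrom <- function(map, chrom) {
  d <- map[map$chrom == chrom, ]
  if (nrow(d) == 0) abort(paste0("chromosome ", chrom, " absent from the genetic map"))
  d
}

#' Cumulative genetic distance at positions
#'
#' Linear interpolation of cumulative cM between flanking markers; positions
#' before the first (after the last) marker clamp to the terminal value, so
#' no genetic distance accrues outside the mapped range.
#'
#' @param map A [genetic_map()].
#' @param chrom Chromosome name (scalar).
#' @param pos Numeric vector of positions (bp).
#' @return Numeric vector of cumulative cM.
#' @export
cumulative_cm_at <- function(map, chrom, pos) {
  d <- map_chrom(map, chrom)
  approx(d$pos, d$cum_cm, xout = pos, rule = 2, ties = "ordered")$y
}

#' Mean recombination rate of intervals
#'
#' For each interval, the rate is the cM accumulated between its endpoints
#' divided by its length in Mb. Intervals entirely outside the map's marker
#' range accrue no cM and are reported as rate 0 with `no_coverage = TRUE`.
#'
#' @param map A [genetic_map()].
#' @param intervals Interval tibble (`chrom`, `start`, `end`).
#' @return The input with columns `rate` (cM/Mb) and `no_coverage` added.
#' @examples
#' m <- genetic_map(tibble::tibble(
#'   chrom = "chr1", pos = c(1000, 2000, 4000), cum_cm = c(0, 0.01, 0.05)
#' ))
#' interval_rate(m, tibble::tibble(chrom = "chr1", start = 1500, end = 3000))
#' @export
interval_rate <- function(map, intervals) {
  intervals <- validate_intervals(intervals)
  rate <- numeric(nrow(intervals))
  nocov <- logical(nrow(intervals))
  for (cn in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == cn)
    d <- map_chrom(map, cn)
    cm <- approx(d$pos, d$cum_cm, xout = c(intervals$start[idx], intervals$end[idx]),
                 rule = 2, ties = "ordered")$y
    n <- length(idx)
    dcm <- cm[(n + 1):(2 * n)] - cm[1:n]
    rate[idx] <- dcm / ((intervals$end[idx] - intervals$start[idx]) / 1e6)
    nocov[idx] <- intervals$end[idx] <= min(d$pos) | intervals$start[idx] >= max(d$pos)
  }
  intervals$rate <- rate
  intervals$no_coverage <- nocov
  intervals
}

#' Mean recombination rate over the unmasked part of intervals
#'
#' Excludes masked bases (e.g. gene bodies padded by 2 kb, to restrict the
#' rate to non-coding sequence): the rate is the cM accumulated over the
#' unmasked sub-segments divided by the unmasked length in Mb. Intervals
#' that are fully masked get `rate = NA` and `fully_masked = TRUE`.
#'
#' @param map A [genetic_map()].
#' @param intervals Interval tibble.
#' @param mask Interval tibble of regions to exclude.
#' @return Input with `rate`, `unmasked_bp`, `fully_masked` columns.
#' @export
interval_rate_masked <- function(map, intervals, mask) {
  intervals <- validate_intervals(intervals)
  if (nrow(mask) > 0) mask <- merge_intervals(mask)
  rate <- rep(NA_real_, nrow(intervals))
  unmasked <- numeric(nrow(intervals))
  for (j in seq_len(nrow(intervals))) {
    segs <- subtract_mask(intervals$chrom[j], intervals$start[j], intervals$end[j], mask)
    unmasked[j] <- sum(segs$end - segs$start)
    if (unmasked[j] == 0) next
    r <- interval_rate(map, tibble(chrom = intervals$chrom[j],
                                   start = segs$start, end = segs$end))
    rate[j] <- sum(r$rate * (segs$end - segs$start) / 1e6) / (unmasked[j] / 1e6)
  }
  intervals$rate <- rate
  intervals$unmasked_bp <- unmasked
  intervals$fully_masked <- unmasked == 0
  intervals
}

# [start,end) minus merged mask rows on `chrom`; returns tibble(start, end)
subtract_mask <- function(chrom, start, end, mask) {
  m <- mask[mask$chrom == chrom & mask$end > start & mask$start < end, ]
  if (nrow(m) == 0) return(tibble(start = start, end = end))
  m <- dplyr::arrange(m, .data$start)
  starts <- c(start, pmin(pmax(m$end, start), end))
  ends <- c(pmin(pmax(m$start, start), end), end)
  keep <- starts < ends
  tibble(start = starts[keep], end = ends[keep])
}

#' Pad intervals symmetrically (e.g. gene bodies +/- 2 kb for masking)
#'
#' @param x Interval tibble.
#' @param pad Bp added on each side; starts floor at 0.
#' @param assembly Optional assembly for clipping at chromosome ends.
#' @return Padded interval tibble.
#' @export
pad_intervals <- function(x, pad, assembly = NULL) {
  x <- validate_intervals(x)
  x$start <- pmax(0, x$start - pad)
  x$end <- x$end + pad
  if (!is.null(assembly)) {
    x$end <- pmin(x$end, assembly_lengths(assembly)[x$chrom])
  }
  x
}
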