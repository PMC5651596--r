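#' Construct a binned feature track
#'
#' A feature track holds one value per fixed-width bin per chromosome
#' (GC fraction, CpG density, SNP density, PRDM9 motif density, gene
#' density, ...). Tracks are the matching space for control sampling: an
#' interval's feature value is the overlap-weighted mean of the bins it
#' covers, and per-feature min-max normalization constants are stored on the
#' track so Euclidean distances between feature vectors are comparable
#' across features.
#'
#' @param x Tibble with columns `chrom`, `start` (bin start, multiple of
#'   `bin_size`), `value` (finite).
#' @param bin_size Bin width in bp (default 1000).
#' @param feature_name Name of the feature.
#' @return A tibble classed `feature_track` with attributes `bin_size`,
#'   `feature_name` and `range` (the min-max normalization constants).
#' @export
feature_track <- function(x, bin_size = 1000, feature_name = "feature") {
  x <- as_tibble(x)[c("chrom", "start", "value")]
  if (any(!is.finite(x$value))) abort("track values must be finite")
  if (any(x$start %% bin_size != 0)) abort("bin starts must be multiples of bin_size")
  x <- dplyr::arrange(x, .data$chrom, .data$start)
  out <- new_tibble_class(x, "feature_track")
  attr(out, "bin_size") <- bin_size
  attr(out, "feature_name") <- feature_name
  attr(out, "range") <- range(x$value)
  out
}

track_bin_size <- function(track) attr(track, "bin_size")
track_name <- function(track) attr(track, "feature_name")
track_range <- function(track) attr(track, "range")

#' Read a bedGraph file into a binned feature track
#'
#' bedGraph rows (0-based half-open) are averaged into fixed bins weighted
#' by overlap. Uncovered bases count as 0 by default — the natural reading
#' for density tracks, where absence of signal is zero signal — or as
#' missing with `uncovered = "missing"` (bins with no covered base become
#' `NA`; such tracks cannot be used for matching).
#'
#' @param path bedGraph path (optionally gzipped).
#' @param assembly A [genome_assembly()]; bins tile every chromosome.
#' @param bin_size Bin width in bp.
#' @param feature_name Feature label.
#' @param uncovered `"zero"` or `"missing"`.
#' @return A [feature_track()].
#' @export
read_track <- function(path, assembly, bin_size = 1000, feature_name = NULL,
                       uncovered = c("zero", "missing")) {
  uncovered <- match.arg(uncovered)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         comment = "#", show_col_types = FALSE, progress = FALSE)
  raw <- validate_intervals(raw, assembly)
  if (is.null(feature_name)) {
    feature_name <- sub("\\.(bedgraph|bdg|txt|tsv)(\\.gz)?$", "",
                        basename(path), ignore.case = TRUE)
  }
  bins <- purrr::map_dfr(seq_len(nrow(assembly)), function(i) {
    n_bin <- ceiling(assembly$length[i] / bin_size)
    tibble(chrom = assembly$chrom[i], start = (seq_len(n_bin) - 1) * bin_size)
  })
  wsum <- setNames(numeric(nrow(bins)), paste0(bins$chrom, ":", bins$start))
  cov <- wsum
  if (nrow(raw) > 0) {
    first_bin <- floor(raw$start / bin_size)
    last_bin <- floor((raw$end - 1) / bin_size)
    n_frag <- last_bin - first_bin + 1
    row_id <- rep(seq_len(nrow(raw)), n_frag)
    bin_id <- first_bin[row_id] + sequence(n_frag) - 1
    frag_start <- pmax(raw$start[row_id], bin_id * bin_size)
    frag_end <- pmin(raw$end[row_id], (bin_id + 1) * bin_size)
    frag_bp <- frag_end - frag_start
    key <- paste0(raw$chrom[row_id], ":", bin_id * bin_size)
    add_w <- tapply(raw$value[row_id] * frag_bp, key, sum)
    add_c <- tapply(frag_bp, key, sum)
    hit <- intersect(names(add_w), names(wsum))
    wsum[hit] <- wsum[hit] + add_w[hit]
    cov[hit] <- cov[hit] + add_c[hit]
  }
  # terminal bins may be shorter than bin_size
  bin_bp <- pmin(bin_size, assembly_lengths(assembly)[bins$chrom] - bins$start)
  bins$value <- if (uncovered == "zero") {
    unname(as.numeric(wsum) / bin_bp)
  } else {
    unname(ifelse(cov > 0, as.numeric(wsum) / cov, NA_real_))
  }
  if (uncovered == "missing") {
    out <- new_tibble_class(dplyr::arrange(bins, .data$chrom, .data$start),
                            "feature_track")
    attr(out, "bin_size") <- bin_size
    attr(out, "feature_name") <- feature_name
    attr(out, "range") <- range(bins$value, na.rm = TRUE)
    return(out)
  }
  feature_track(bins, bin_size = bin_size, feature_name = feature_name)
}

# Overlap-weighted mean of track values over each interval. Uses the prefix
# integral of the piecewise-constant bin values, so cost is O(1) per interval.
track_interval_means <- function(track, intervals) {
  b <- track_bin_size(track)
  out <- rep(NA_real_, nrow(intervals))
  for (cn in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == cn)
    v <- track$value[track$chrom == cn]
    if (length(v) == 0) next
    cum <- c(0, cumsum(v)) * b  # integral up to each bin boundary
    integ <- function(p) {
      bin <- pmin(floor(p / b), length(v) - 1)
      cum[bin + 1] + v[bin + 1] * (p - bin * b)
    }
    out[idx] <- (integ(intervals$end[idx]) - integ(intervals$start[idx])) /
      (intervals$end[idx] - intervals$start[idx])
  }
  out
}

# Feature matrix (intervals x tracks) of normalized [0,1] values using each
# track's stored min-max range.
feature_matrix <- function(tracks, intervals, normalize = TRUE) {
  m <- vapply(tracks, function(tr) {
    v <- track_interval_means(tr, intervals)
    if (normalize) {
      r <- track_range(tr)
      if (diff(r) > 0) v <- (v - r[1]) / (r[2] - r[1]) else v <- rep(0, length(v))
    }
    v
  }, numeric(nrow(intervals)))
  if (nrow(intervals) == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- vapply(tracks, track_name, character(1))
  m
}

#' Construct a CpG methylation track
#'
#' @param x Tibble with columns `chrom`, `pos` (CpG position, bp) and
#'   `level` (methylation fraction in \[0, 1\]).
#' @return A tibble classed `methylation_track`.
#' @export
methylation_track <- function(x) {
  x <- as_tibble(x)[c("chrom", "pos", "level")]
  if (any(x$level < 0 | x$level > 1, na.rm = TRUE)) {
    abort("methylation levels must lie in [0, 1]")
  }
  x <- dplyr::arrange(x, .data$chrom, .data$pos)
  dup <- unlist(tapply(x$pos, x$chrom, function(p) c(FALSE, diff(p) <= 0)))
  if (any(dup)) abort("CpG positions must be strictly increasing per chromosome")
  new_tibble_class(x, "methylation_track")
}

#' Read a methylation bedGraph (chrom, start, end, level)
#'
#' The CpG position is taken as the row start (0-based).
#' @param path bedGraph path.
#' @param assembly Optional assembly for validation.
#' @return A [methylation_track()].
#' @export
read_methylation <- function(path, assembly = NULL) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "level"),
                         comment = "#", show_col_types = FALSE, progress = FALSE)
  raw <- validate_intervals(raw, assembly)
  methylation_track(tibble(chrom = raw$chrom, pos = raw$start, level = raw$level))
}

#' @rdname read_methylation
#' @param x A [methylation_track()].
#' @export
write_methylation <- function(x, path) {
  readr::write_tsv(tibble(chrom = x$chrom, start = x$pos, end = x$pos + 1,
                          level = x$level),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# Mean methylation level over each interval (CpGs with pos in [start,end));
# NA where an interval contains no CpG.
methylation_interval_means <- function(meth, intervals) {
  out <- rep(NA_real_, nrow(intervals))
  for (cn in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == cn)
    d <- meth[meth$chrom == cn, ]
    if (nrow(d) == 0) next
    cumlev <- c(0, cumsum(d$level))
    lo <- findInterval(intervals$start[idx] - 0.5, d$pos)
    hi <- findInterval(intervals$end[idx] - 0.5, d$pos)
    n <- hi - lo
    out[idx] <- ifelse(n > 0, (cumlev[hi + 1] - cumlev[lo + 1]) / n, NA_real_)
  }
  out
}

# ---- per-window means, for genome-scan correlations -------------------------

#' Per-window mean values of a genomic signal
#'
#' Tiles each chromosome with non-overlapping windows and returns the mean
#' signal per window. Methods exist for [feature_track()] (overlap-weighted
#' bin mean), [methylation_track()] (mean CpG level; `NA` when a window has
#' no CpG) and [genetic_map()] (mean recombination rate in cM/Mb; `NA` for
#' windows outside the mapped range).
#'
#' @param x The signal object.
#' @param assembly A [genome_assembly()].
#' @param window Window size in bp.
#' @return Tibble with `chrom`, `start`, `end`, `mean_value`.
#' @export
window_means <- function(x, assembly, window) UseMethod("window_means")

window_grid <- function(assembly, window) {
  purrr::map_dfr(seq_len(nrow(assembly)), function(i) {
    s <- seq(0, assembly$length[i] - 1, by = window)
    tibble(chrom = assembly$chrom[i], start = s,
           end = pmin(s + window, assembly$length[i]))
  })
}

#' @export
window_means.feature_track <- function(x, assembly, window) {
  g <- window_grid(assembly, window)
  g$mean_value <- track_interval_means(x, g)
  g
}

#' @export
window_means.methylation_track <- function(x, assembly, window) {
  g <- window_grid(assembly, window)
  g$mean_value <- methylation_interval_means(x, g)
  g
}

#' @export
window_means.genetic_map <- function(x, assembly, window) {
  g <- window_grid(assembly, window)
  r <- interval_rate(x, g)
  g$mean_value <- ifelse(r$no_coverage, NA_real_, r$rate)
  g
}
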