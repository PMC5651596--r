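#' Validate a table of genomic intervals
#'
#' Checks the package-wide interval contract: columns `chrom`, `start`,
#' `end`; `0 <= start < end`; and, when an assembly is supplied, `end` within
#' the chromosome length. Intervals running past a chromosome end are clipped
#' with a warning (files in the wild frequently overhang by a bin).
#'
#' @param x A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param assembly Optional [genome_assembly()] to validate/clip against.
#' @return The validated (possibly clipped) tibble.
#' @export
validate_intervals <- function(x, assembly = NULL) {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("interval table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    abort(paste0("invalid interval at row ", bad[1],
                 ": need 0 <= start < end"))
  }
  if (!is.null(assembly)) {
    check_chroms_known(x$chrom, assembly)
    len <- assembly_lengths(assembly)[x$chrom]
    over <- which(x$end > len)
    if (length(over) > 0) {
      warn(paste0(length(over), " interval(s) extend past the chromosome end; clipped"))
      x$end[over] <- len[over]
      x <- dplyr::filter(x, .data$start < .data$end)
    }
  }
  x
}

#' Read genomic intervals from a BED file
#'
#' Reads BED3+ (plain or gzip). BED is already 0-based half-open, matching
#' the internal convention, so coordinates pass through unchanged. Extra
#' columns (name, score, strand) are kept when present.
#'
#' @param path Path to a BED file (optionally gzipped).
#' @param assembly Optional [genome_assembly()] to validate against.
#' @return A tibble with columns `chrom`, `start`, `end` (+ `name`, `score`
#'   when present).
#' @export
read_intervals <- function(path, assembly = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 3) abort("BED file needs at least 3 columns")
  bed_names <- c("chrom", "start", "end", "name", "score", "strand")
  names(raw)[seq_len(min(ncol(raw), 6))] <- bed_names[seq_len(min(ncol(raw), 6))]
  raw$chrom <- as.character(raw$chrom)
  raw$start <- as.numeric(raw$start)
  raw$end <- as.numeric(raw$end)
  validate_intervals(raw, assembly)
}

#' Write genomic intervals to a BED file
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optionally more).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  x <- validate_intervals(x)
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  readr::write_tsv(x[keep], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# ---- interval arithmetic (sorted-vector implementations) --------------------

#' Merge overlapping or touching intervals
#'
#' @param x Interval tibble.
#' @return Tibble of disjoint intervals sorted by (chrom, start).
#' @export
merge_intervals <- function(x) {
  x <- validate_intervals(x)[c("chrom", "start", "end")]
  x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end)
  dplyr::group_by(x, .data$chrom) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      if (n <= 1) return(d)
      keep_start <- d$start
      keep_end <- d$end
      grp <- cumsum(c(TRUE, keep_start[-1] > cummax(keep_end)[-n]))
      tibble(start = tapply(keep_start, grp, min)[unique(grp)] |> as.numeric(),
             end = tapply(keep_end, grp, max)[unique(grp)] |> as.numeric())
    }) |>
    dplyr::ungroup()
}

# Total bp of `query` covered by the merged interval set `subject`.
# Both are interval tibbles; returns a numeric vector along rows of `query`.
interval_coverage_bp <- function(query, subject) {
  if (nrow(subject) == 0) return(rep(0, nrow(query)))
  subject <- merge_intervals(subject)
  out <- numeric(nrow(query))
  for (cn in unique(query$chrom)) {
    qi <- which(query$chrom == cn)
    s <- subject[subject$chrom == cn, ]
    if (nrow(s) == 0) next
    for (j in qi) {
      ov <- pmin(query$end[j], s$end) - pmax(query$start[j], s$start)
      out[j] <- sum(ov[ov > 0])
    }
  }
  out
}

# TRUE for each row of x fully contained in some row of `container`.
intervals_contained <- function(x, container) {
  out <- logical(nrow(x))
  for (cn in unique(x$chrom)) {
    xi <- which(x$chrom == cn)
    s <- container[container$chrom == cn, ]
    if (nrow(s) == 0) next
    for (j in xi) {
      out[j] <- any(s$start <= x$start[j] & x$end[j] <= s$end)
    }
  }
  out
}

# TRUE for each row of x overlapping (>=1 bp) any row of `other`.
intervals_overlap_any <- function(x, other) {
  cov <- interval_coverage_bp(x, other)
  cov > 0
}

interval_midpoints <- function(x) (x$start + x$end) / 2
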