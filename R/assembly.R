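#' Define a genome assembly
#'
#' An assembly is the coordinate system every other object is validated
#' against: an ordered set of chromosomes with their lengths in base pairs.
#' All coordinates in the package are 0-based, half-open `[start, end)`;
#' 1-based file formats are converted at the I/O boundary.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer-ish vector of chromosome lengths in bp (> 0).
#'
#' @return A tibble with columns `chrom` and `length`, classed
#'   `genome_assembly`.
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(2e7, 2e7))
#' @export
genome_assembly <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) abort("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort("chromosome lengths must be positive and finite")
  }
  new_tibble_class(tibble(chrom = chrom, length = length), "genome_assembly")
}

new_tibble_class <- function(x, cls) {
  class(x) <- c(cls, class(tibble()))
  x
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", nrow(x), " chromosome(s), ",
      format(sum(x$length), big.mark = ","), " bp total\n", sep = "")
  NextMethod()
}

assembly_lengths <- function(assembly) {
  setNames(assembly$length, assembly$chrom)
}

check_chroms_known <- function(chrom, assembly, what = "interval") {
  unknown <- setdiff(unique(chrom), assembly$chrom)
  if (length(unknown) > 0) {
    abort(paste0(what, "(s) on chromosome(s) absent from the assembly: ",
                 paste(unknown, collapse = ", ")))
  }
  invisible(TRUE)
}
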