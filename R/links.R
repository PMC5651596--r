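#' Distance class boundaries
#'
#' Links are stratified by anchor-midpoint distance into short (1-10 kb),
#' medium (10-100 kb) and long (100 kb - 1 Mb) classes; distances below 1 kb
#' or above 1 Mb are excluded from analysis. Classes are half-open on the
#' left boundaries and closed at 1 Mb.
#'
#' @param distance Numeric vector of distances in bp.
#' @return Factor with levels `SHORT`, `MEDIUM`, `LONG`, `EXCLUDED`.
#' @examples
#' distance_class(c(500, 5e3, 6e4, 1e6, 2e6))
#' @export
distance_class <- function(distance) {
  cls <- dplyr::case_when(
    distance >= 1e3 & distance < 1e4 ~ "SHORT",
    distance >= 1e4 & distance < 1e5 ~ "MEDIUM",
    distance >= 1e5 & distance <= 1e6 ~ "LONG",
    TRUE ~ "EXCLUDED"
  )
  factor(cls, levels = c("SHORT", "MEDIUM", "LONG", "EXCLUDED"))
}

LINK_TYPES <- c("eQTL", "meQTL", "HiC", "ChIAPET", "DNase_TSS", "enhancer_TSS", "other")

#' Build a link table
#'
#' A link joins two anchors on the same chromosome (a regulatory variant or
#' element and its target). Anchors are stored left-to-right by midpoint;
#' derived columns are added: the span (closed hull of both anchors), the
#' midpoint distance, and its [distance_class()].
#'
#' @param x Tibble with columns `chrom`, `start_a`, `end_a`, `start_b`,
#'   `end_b`; optionally `link_type`, `score`, `target_id`.
#' @param link_type Default link type when the column is absent.
#' @return A tibble classed `links` with derived columns `span_start`,
#'   `span_end`, `distance`, `distance_class`.
#' @export
as_links <- function(x, link_type = "other") {
  x <- as_tibble(x)
  need <- c("chrom", "start_a", "end_a", "start_b", "end_b")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) abort(paste0("link table lacks column(s): ",
                                     paste(miss, collapse = ", ")))
  if (!"link_type" %in% names(x)) x$link_type <- link_type
  if (!all(x$link_type %in% LINK_TYPES)) {
    abort(paste0("link_type must be one of: ", paste(LINK_TYPES, collapse = ", ")))
  }
  if (!"score" %in% names(x)) x$score <- NA_real_
  if (!"target_id" %in% names(x)) x$target_id <- NA_character_
  bad <- which(x$start_a < 0 | x$start_a >= x$end_a | x$start_b < 0 |
                 x$start_b >= x$end_b)
  if (length(bad) > 0) abort(paste0("invalid anchor at row ", bad[1]))
  # canonical order: anchor_a leftmost by midpoint
  mid_a <- (x$start_a + x$end_a) / 2
  mid_b <- (x$start_b + x$end_b) / 2
  swap <- mid_a > mid_b
  if (any(swap)) {
    tmp_s <- x$start_a[swap]; tmp_e <- x$end_a[swap]
    x$start_a[swap] <- x$start_b[swap]; x$end_a[swap] <- x$end_b[swap]
    x$start_b[swap] <- tmp_s; x$end_b[swap] <- tmp_e
  }
  relink(new_tibble_class(x, "links"))
}

# recompute derived geometry after any anchor edit
relink <- function(x) {
  x$span_start <- pmin(x$start_a, x$start_b)
  x$span_end <- pmax(x$end_a, x$end_b)
  x$distance <- abs((x$start_b + x$end_b) / 2 - (x$start_a + x$end_a) / 2)
  x$distance_class <- distance_class(x$distance)
  x
}

#' @export
print.links <- function(x, ...) {
  cat("<links> ", nrow(x), " link(s); classes: ",
      paste(names(table(x$distance_class)), as.integer(table(x$distance_class)),
            sep = "=", collapse = " "), "\n", sep = "")
  NextMethod()
}

# span intervals of a link table, as a plain interval tibble
link_spans <- function(links) {
  tibble(chrom = links$chrom, start = links$span_start, end = links$span_end)
}

#' Read a link set from file
#'
#' Two formats:
#' * `bedpe` — chrom1, start1, end1, chrom2, start2, end2 \[, name, score\].
#' * `two_point` — chrom, posA, posB, score \[, target_id\]; positions are
#'   0-based point coordinates and become 1-bp anchors.
#'
#' Inter-chromosomal BEDPE rows are dropped with a message giving the count;
#' the analysis is defined on same-chromosome spans only.
#'
#' @param path Path (optionally gzipped).
#' @param format `"bedpe"` or `"two_point"`.
#' @param link_type Link type tag applied to all rows.
#' @param assembly Optional assembly for validation.
#' @return A [as_links()] tibble.
#' @export
read_links <- function(path, format = c("bedpe", "two_point"),
                       link_type = "other", assembly = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (format == "bedpe") {
    if (ncol(raw) < 6) abort("BEDPE needs >= 6 columns")
    names(raw)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
    inter <- raw$chrom1 != raw$chrom2
    if (any(inter)) {
      inform(paste0("dropped ", sum(inter), " inter-chromosomal link(s)"))
      raw <- raw[!inter, ]
    }
    out <- tibble(chrom = as.character(raw$chrom1),
                  start_a = as.numeric(raw$start1), end_a = as.numeric(raw$end1),
                  start_b = as.numeric(raw$start2), end_b = as.numeric(raw$end2))
    if (ncol(raw) >= 8) out$score <- as.numeric(raw[[8]])
    if (ncol(raw) >= 7) out$target_id <- as.character(raw[[7]])
  } else {
    if (ncol(raw) < 4) abort("two_point format needs >= 4 columns")
    pa <- suppressWarnings(as.numeric(raw[[2]]))
    pb <- suppressWarnings(as.numeric(raw[[3]]))
    bad <- which(is.na(pa) | is.na(pb) | pa < 0 | pb < 0)
    if (length(bad) > 0) abort(paste0("malformed coordinates at row ", bad[1]))
    out <- tibble(chrom = as.character(raw[[1]]),
                  start_a = pa, end_a = pa + 1,
                  start_b = pb, end_b = pb + 1,
                  score = as.numeric(raw[[4]]))
    if (ncol(raw) >= 5) out$target_id <- as.character(raw[[5]])
  }
  if (!is.null(assembly)) {
    check_chroms_known(out$chrom, assembly, "link")
    len <- assembly_lengths(assembly)[out$chrom]
    if (any(out$end_a > len | out$end_b > len)) {
      abort("link anchor beyond chromosome end")
    }
  }
  as_links(out, link_type = link_type)
}

#' Write a link set as BEDPE
#'
#' @param links A link table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_links <- function(links, path) {
  readr::write_tsv(
    tibble(chrom1 = links$chrom, start1 = links$start_a, end1 = links$end_a,
           chrom2 = links$chrom, start2 = links$start_b, end2 = links$end_b,
           name = ifelse(is.na(links$target_id), ".", links$target_id),
           score = links$score),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
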