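#' Mean recombination rate by link distance
#'
#' Bins links by anchor distance (equal-width bins within each distance
#' class) and reports the per-bin mean span rate with the confidence band
#' used throughout the figures: half-width = sd x 1.96 / 10, with sd the
#' sample standard deviation (0 for a single link). Empty bins are emitted
#' with `n = 0` and missing mean.
#'
#' @param links A link table.
#' @param map A [genetic_map()].
#' @param n_bins Bins per distance class (default 100).
#' @param controls Optional control tibble (e.g. from
#'   [sample_length_matched()]); adds `mean_control` per bin.
#' @return Tibble classed `rate_by_distance`: `distance_class`, `bin`,
#'   `bin_mid`, `n`, `mean_rate`, `ci_half` (+ control columns when given).
#' @export
mean_rate_by_distance <- function(links, map, n_bins = 100, controls = NULL) {
  if (nrow(links) == 0) abort("no links")
  if (n_bins < 1) abort("n_bins must be >= 1")
  rates <- interval_rate(map, link_spans(links))$rate
  ctrl_rates <- if (!is.null(controls)) {
    cr <- rep(NA_real_, nrow(links))
    cr[controls$link_id] <- interval_rate(map, controls)$rate
    cr
  }
  sd0 <- function(x) if (length(x) <= 1) 0 else sd(x)
  out <- purrr::map_dfr(c("SHORT", "MEDIUM", "LONG"), function(cl) {
    b <- class_bounds(cl)
    lo <- b[1]; hi <- b[2] + 1
    edges <- seq(lo, hi, length.out = n_bins + 1)
    in_cl <- which(as.character(links$distance_class) == cl)
    bin_of <- pmin(findInterval(links$distance[in_cl], edges), n_bins)
    purrr::map_dfr(seq_len(n_bins), function(k) {
      sel <- in_cl[bin_of == k]
      row <- tibble(distance_class = cl, bin = k,
                    bin_mid = (edges[k] + edges[k + 1]) / 2,
                    n = length(sel),
                    mean_rate = if (length(sel) > 0) mean(rates[sel]) else NA_real_,
                    ci_half = if (length(sel) > 0) sd0(rates[sel]) * 1.96 / 10 else NA_real_)
      if (!is.null(ctrl_rates)) {
        cc <- ctrl_rates[sel]
        cc <- cc[!is.na(cc)]
        row$mean_control <- if (length(cc) > 0) mean(cc) else NA_real_
        row$ci_half_control <- if (length(cc) > 0) sd0(cc) * 1.96 / 10 else NA_real_
      }
      row
    })
  })
  new_tibble_class(out, "rate_by_distance")
}

#' Recombination hotspot density of intervals
#'
#' Counts hotspot intervals whose midpoint falls inside each query interval
#' and divides by the query length in kb. Midpoint containment avoids
#' double-counting a hotspot across adjacent queries.
#'
#' @param intervals Interval tibble.
#' @param hotspots Interval tibble of hotspot calls.
#' @return Numeric vector, hotspots per kb, along rows of `intervals`.
#' @export
hotspot_density <- function(intervals, hotspots) {
  out <- numeric(nrow(intervals))
  for (cn in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == cn)
    mids <- sort(interval_midpoints(hotspots[hotspots$chrom == cn, ]))
    if (length(mids) == 0) next
    cnt <- findInterval(intervals$end[idx] - 1e-9, mids) -
      findInterval(intervals$start[idx] - 1e-9, mids)
    out[idx] <- cnt / ((intervals$end[idx] - intervals$start[idx]) / 1000)
  }
  out
}
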