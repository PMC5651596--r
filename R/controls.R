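#' Length-matched random control intervals
#'
#' For each link, draws one random interval with exactly the same physical
#' length on the same chromosome, start uniform over the feasible range.
#' This is the baseline matched control against which link-span
#' recombination rates are compared.
#'
#' @param links A link table.
#' @param assembly A [genome_assembly()].
#' @return A control tibble: `link_id`, `chrom`, `start`, `end`,
#'   `feature_distance` (NA here), `iterations` (1), `matched` (TRUE).
#' @export
sample_length_matched <- function(links, assembly) {
  len <- assembly_lengths(assembly)[links$chrom]
  L <- links$span_end - links$span_start
  if (any(L > len)) abort("link span longer than its chromosome")
  start <- floor(runif(nrow(links), 0, len - L + 1))
  start <- pmin(start, len - L)  # guard the degenerate runif upper edge
  tibble(link_id = seq_len(nrow(links)), chrom = links$chrom,
         start = start, end = start + L,
         feature_distance = NA_real_, iterations = 1L, matched = TRUE)
}

# Cache per-track, per-chromosome prefix integrals so the rejection sampler
# can score thousands of candidate intervals per link cheaply.
track_integrals <- function(tracks) {
  purrr::map(tracks, function(tr) {
    b <- track_bin_size(tr)
    r <- track_range(tr)
    chroms <- unique(tr$chrom)
    per_chrom <- purrr::map(setNames(chroms, chroms), function(cn) {
      v <- tr$value[tr$chrom == cn]
      list(v = v, cum = c(0, cumsum(v)) * b)
    })
    list(bin = b, range = r, name = track_name(tr), per_chrom = per_chrom)
  })
}

# Normalized feature matrix for same-chromosome intervals, from cached
# integrals. starts/ends numeric vectors.
fm_fast <- function(integrals, chrom, starts, ends) {
  m <- vapply(integrals, function(ti) {
    pc <- ti$per_chrom[[chrom]]
    if (is.null(pc)) return(rep(0, length(starts)))
    b <- ti$bin
    integ <- function(p) {
      bin <- pmin(floor(p / b), length(pc$v) - 1)
      pc$cum[bin + 1] + pc$v[bin + 1] * (p - bin * b)
    }
    v <- (integ(ends) - integ(starts)) / (ends - starts)
    if (diff(ti$range) > 0) (v - ti$range[1]) / diff(ti$range) else rep(0, length(v))
  }, numeric(length(starts)))
  if (length(starts) == 1) m <- matrix(m, nrow = 1)
  m
}

#' Feature-matched controls by rejection sampling
#'
#' For each link, repeatedly draws length-matched random intervals on the
#' same chromosome and accepts the first whose Euclidean distance to the
#' link span in normalized feature space (GC, CpG density, SNP density,
#' PRDM9 motif density, ... — whatever tracks are supplied) is below
#' `tolerance`. Each feature is min-max normalized to \[0, 1\] using the
#' track's own range before the distance is taken, so the tolerance is
#' dimensionless. On exhaustion (`max_iter` draws) the best candidate seen
#' is returned with `matched = FALSE`.
#'
#' @param links A link table.
#' @param assembly A [genome_assembly()].
#' @param tracks List of [feature_track()]s; empty list degrades to pure
#'   length matching with a warning.
#' @param tolerance Acceptance radius in normalized feature space
#'   (default 0.01).
#' @param max_iter Maximum draws per link (default 10000).
#' @param batch Candidate draws evaluated per vectorized round.
#' @return Control tibble as in [sample_length_matched()], with
#'   `feature_distance`, `iterations`, `matched` filled in.
#' @export
sample_feature_matched_rejection <- function(links, assembly, tracks,
                                             tolerance = 0.01, max_iter = 10000,
                                             batch = 256) {
  if (tolerance < 0) abort("tolerance must be >= 0")
  if (max_iter < 1) abort("max_iter must be >= 1")
  if (length(tracks) == 0) {
    warn("no feature tracks supplied; falling back to length matching")
    return(sample_length_matched(links, assembly))
  }
  ints <- track_integrals(tracks)
  chrom_len <- assembly_lengths(assembly)
  target <- fm_fast_multi(ints, links)
  n <- nrow(links)
  out_start <- numeric(n); out_dist <- numeric(n)
  out_iter <- integer(n); out_matched <- logical(n)
  L <- links$span_end - links$span_start
  for (j in seq_len(n)) {
    cn <- links$chrom[j]
    max_start <- chrom_len[[cn]] - L[j]
    best_d <- Inf; best_s <- 0; used <- 0L; ok <- FALSE
    while (used < max_iter) {
      nb <- min(batch, max_iter - used)
      s <- pmin(floor(runif(nb, 0, max_start + 1)), max_start)
      fm <- fm_fast(ints, cn, s, s + L[j])
      d <- sqrt(rowSums((fm - matrix(target[j, ], nb, ncol(fm), byrow = TRUE))^2))
      hit <- which(d < tolerance)
      if (length(hit) > 0) {
        used <- used + hit[1]
        best_d <- d[hit[1]]; best_s <- s[hit[1]]; ok <- TRUE
        break
      }
      used <- used + nb
      if (min(d) < best_d) {
        best_d <- min(d); best_s <- s[which.min(d)]
      }
    }
    out_start[j] <- best_s; out_dist[j] <- best_d
    out_iter[j] <- used; out_matched[j] <- ok
  }
  tibble(link_id = seq_len(n), chrom = links$chrom,
         start = out_start, end = out_start + L,
         feature_distance = out_dist, iterations = out_iter,
         matched = out_matched)
}

# normalized feature rows for each link's span (possibly across chromosomes)
fm_fast_multi <- function(ints, links) {
  out <- matrix(0, nrow(links), length(ints))
  for (cn in unique(links$chrom)) {
    idx <- which(links$chrom == cn)
    out[idx, ] <- fm_fast(ints, cn, links$span_start[idx], links$span_end[idx])
  }
  out
}

#' Enumerate a candidate index for k-d tree control matching
#'
#' Enumerates, per chromosome, every interval whose start lies on a regular
#' grid and whose length runs over a regular ladder (the classical
#' enumeration is a 1-kb grid with lengths 1 kb to 1 Mb in 1-kb steps),
#' computes each candidate's normalized feature vector (supplied tracks
#' plus interval length), and indexes the candidates in a k-d tree per
#' chromosome. Querying by chromosome makes chromosome an exact matching
#' feature; length participates as a normalized coordinate.
#'
#' @param assembly A [genome_assembly()].
#' @param tracks List of [feature_track()]s.
#' @param grid Start grid spacing in bp (default 1000).
#' @param length_range Candidate lengths, c(min, max) bp (default 1 kb -
#'   1 Mb).
#' @param length_step Length ladder step in bp (default 1000).
#' @param subsample Keep every `subsample`-th candidate (default 1 = all).
#' @param max_candidates Guard: error when the enumeration would exceed
#'   this without subsampling (default 2e6).
#' @return A `candidate_index` object.
#' @export
build_candidate_index <- function(assembly, tracks, grid = 1000,
                                  length_range = c(1000, 1e6),
                                  length_step = 1000, subsample = 1,
                                  max_candidates = 2e6) {
  if (grid < 1 || length_step < 1) abort("grid and length_step must be >= 1")
  lens_all <- seq(length_range[1], length_range[2], by = length_step)
  total <- sum(vapply(seq_len(nrow(assembly)), function(i) {
    sum(pmax(0, floor((assembly$length[i] - lens_all) / grid) + 1))
  }, numeric(1))) / subsample
  if (total > max_candidates) {
    abort(paste0("enumeration would create ~", format(round(total), big.mark = ","),
                 " candidates (> max_candidates = ",
                 format(max_candidates, big.mark = ","),
                 "); raise `subsample` or the cap"))
  }
  ints <- track_integrals(tracks)
  len_norm <- function(L) {
    if (diff(length_range) > 0) (L - length_range[1]) / diff(length_range) else 0
  }
  per_chrom <- purrr::map(setNames(seq_len(nrow(assembly)), assembly$chrom),
                          function(i) {
    clen <- assembly$length[i]
    cn <- assembly$chrom[i]
    lens <- lens_all[lens_all <= clen]
    starts <- unlist(lapply(lens, function(L) seq(0, clen - L, by = grid)))
    lengths <- rep(lens, vapply(lens, function(L) length(seq(0, clen - L, by = grid)),
                                numeric(1)))
    if (subsample > 1) {
      keep <- seq(1, length(starts), by = subsample)
      starts <- starts[keep]; lengths <- lengths[keep]
    }
    feats <- cbind(fm_fast(ints, cn, starts, starts + lengths),
                   length = len_norm(lengths))
    list(intervals = tibble(chrom = cn, start = starts, end = starts + lengths),
         feats = feats, tree = kdtree_build(feats))
  })
  structure(list(per_chrom = per_chrom, integrals = ints,
                 length_range = length_range),
            class = "candidate_index")
}

#' @export
print.candidate_index <- function(x, ...) {
  n <- sum(vapply(x$per_chrom, function(p) nrow(p$intervals), numeric(1)))
  cat("<candidate_index> ", format(n, big.mark = ","), " candidates on ",
      length(x$per_chrom), " chromosome(s), ",
      ncol(x$per_chrom[[1]]$feats), " features\n", sep = "")
  invisible(x)
}

# interval-to-interval gap (0 if overlapping) and overlap fraction of the
# shorter interval, vectorized over candidate rows
candidate_proximity <- function(cand, span_start, span_end) {
  ov <- pmin(cand$end, span_end) - pmax(cand$start, span_start)
  shorter <- pmin(cand$end - cand$start, span_end - span_start)
  gap <- pmax(0, pmax(cand$start - span_end, span_start - cand$end))
  list(gap = gap, overlap_frac = pmax(0, ov) / shorter,
       overlapping = ov > 0)
}

#' k-d tree matched controls
#'
#' For each link, queries the `k` nearest candidates (default 1000) in
#' normalized feature space on the link's chromosome, drops candidates too
#' close to the link itself — non-overlapping candidates less than 1 kb
#' away, or candidates overlapping more than 50 percent of the shorter of
#' the two intervals — optionally drops candidates overlapping a CTCF
#' motif, and returns one of the survivors uniformly at random. When every
#' candidate is filtered, the query is retried with 2k, 4k, ... up to the
#' candidate count before giving up with an error.
#'
#' @param index A [build_candidate_index()] result.
#' @param links A link table.
#' @param k Number of neighbours to query (default 1000).
#' @param ctcf_motifs Optional interval tibble; candidates overlapping any
#'   motif are excluded.
#' @return Control tibble (`link_id`, `chrom`, `start`, `end`,
#'   `feature_distance`, `iterations` = neighbours examined, `matched`).
#' @export
sample_kdtree_matched <- function(index, links, k = 1000, ctcf_motifs = NULL) {
  if (k < 1) abort("k must be >= 1")
  target <- fm_fast_multi(index$integrals, links)
  lr <- index$length_range
  L <- links$span_end - links$span_start
  len_norm <- if (diff(lr) > 0) (L - lr[1]) / diff(lr) else rep(0, length(L))
  target <- cbind(target, len_norm)
  out <- vector("list", nrow(links))
  for (j in seq_len(nrow(links))) {
    pc <- index$per_chrom[[links$chrom[j]]]
    if (is.null(pc)) abort(paste0("chromosome ", links$chrom[j], " not in index"))
    n_cand <- nrow(pc$intervals)
    kk <- min(k, n_cand)
    repeat {
      res <- kdtree_query(pc$tree, matrix(target[j, ], 1), kk)
      cand <- pc$intervals[res$idx[1, ], ]
      prox <- candidate_proximity(cand, links$span_start[j], links$span_end[j])
      keep <- !((prox$gap < 1000 & !prox$overlapping) | prox$overlap_frac > 0.5)
      if (!is.null(ctcf_motifs) && any(keep)) {
        keep[keep] <- !intervals_overlap_any(cand[keep, ], ctcf_motifs)
      }
      if (any(keep)) {
        pick <- which(keep)[sample.int(sum(keep), 1)]
        out[[j]] <- tibble(link_id = j, chrom = links$chrom[j],
                           start = cand$start[pick], end = cand$end[pick],
                           feature_distance = res$dist[1, pick],
                           iterations = kk, matched = TRUE)
        break
      }
      if (kk >= n_cand) {
        abort(paste0("all ", n_cand, " candidates filtered for link ", j))
      }
      kk <- min(2 * kk, n_cand)
    }
  }
  dplyr::bind_rows(out)
}

#' Domain-constrained matched controls
#'
#' Draws, for each link, a random interval of exactly the span's length
#' inside the domain (e.g. a chromatin loop call) that contains the span;
#' when several domains contain it the smallest wins. Links contained in no
#' domain are skipped with a warning.
#'
#' @param links A link table.
#' @param domains Interval tibble of domains.
#' @return Control tibble; skipped links are absent (their `link_id`s do not
#'   appear).
#' @export
sample_within_domain <- function(links, domains) {
  out <- vector("list", nrow(links))
  n_skip <- 0L
  for (j in seq_len(nrow(links))) {
    d <- domains[domains$chrom == links$chrom[j] &
                   domains$start <= links$span_start[j] &
                   domains$end >= links$span_end[j], ]
    if (nrow(d) == 0) { n_skip <- n_skip + 1L; next }
    d <- d[which.min(d$end - d$start), ]
    L <- links$span_end[j] - links$span_start[j]
    s <- min(floor(runif(1, d$start, d$end - L + 1)), d$end - L)
    out[[j]] <- tibble(link_id = j, chrom = links$chrom[j],
                       start = s, end = s + L,
                       feature_distance = NA_real_, iterations = 1L,
                       matched = TRUE)
  }
  if (n_skip > 0) warn(paste0(n_skip, " link(s) contained in no domain; skipped"))
  dplyr::bind_rows(out)
}

class_bounds <- function(dist_class) {
  switch(as.character(dist_class),
         SHORT = c(1e3, 1e4 - 1),
         MEDIUM = c(1e4, 1e5 - 1),
         LONG = c(1e5, 1e6),
         abort(paste0("no pair universe for class ", dist_class)))
}

#' Sample random point pairs from the distance-constrained pair universe
#'
#' The null universe is every same-chromosome pair (a, b) — a from
#' `points_a` (e.g. genotyped SNPs), b from `points_b` (e.g. TSSs) — whose
#' distance falls in the requested distance class. Pairs are drawn
#' uniformly from this universe without materializing the cross product:
#' per-`a` feasible-window counts (via sorted `points_b`) weight the choice
#' of `a`, then the b within the window is picked by index arithmetic.
#'
#' @param points_a,points_b Tibbles with `chrom`, `pos`.
#' @param n Number of pairs to draw (with replacement).
#' @param dist_class `"SHORT"`, `"MEDIUM"` or `"LONG"`.
#' @return Tibble of hull intervals: `chrom`, `start`, `end`, `pos_a`,
#'   `pos_b`, `distance`.
#' @export
sample_null_pairs <- function(points_a, points_b, n, dist_class) {
  bounds <- class_bounds(dist_class)
  lo <- bounds[1]; hi <- bounds[2]
  chroms <- intersect(unique(points_a$chrom), unique(points_b$chrom))
  per <- purrr::map(chroms, function(cn) {
    a <- points_a$pos[points_a$chrom == cn]
    b <- sort(points_b$pos[points_b$chrom == cn])
    iLlo <- findInterval(a - hi - 0.5, b)   # b < a - hi
    iLhi <- findInterval(a - lo + 0.5, b)   # b <= a - lo
    iRlo <- findInterval(a + lo - 0.5, b)   # b < a + lo
    iRhi <- findInterval(a + hi + 0.5, b)   # b <= a + hi
    nL <- iLhi - iLlo
    nR <- iRhi - iRlo
    list(chrom = cn, a = a, b = b, nL = nL, nR = nR,
         iLlo = iLlo, iRlo = iRlo, w = nL + nR)
  })
  W <- vapply(per, function(p) sum(p$w), numeric(1))
  if (sum(W) == 0) {
    abort(paste0("no feasible pair in distance class ", dist_class))
  }
  # flatten: choose (chrom, a-index) with probability proportional to weight
  all_w <- unlist(purrr::map(per, "w"))
  owner <- rep(seq_along(per), vapply(per, function(p) length(p$a), numeric(1)))
  within <- unlist(purrr::map(per, function(p) seq_along(p$a)))
  pick <- sample.int(length(all_w), n, replace = TRUE, prob = all_w)
  u <- floor(runif(n) * all_w[pick]) + 1  # uniform in 1..w
  res_chrom <- character(n); res_a <- numeric(n); res_b <- numeric(n)
  for (ci in unique(owner[pick])) {
    p <- per[[ci]]
    sel <- which(owner[pick] == ci)
    ai <- within[pick[sel]]
    uu <- u[sel]
    left <- uu <= p$nL[ai]
    bidx <- ifelse(left, p$iLlo[ai] + uu, p$iRlo[ai] + (uu - p$nL[ai]))
    res_chrom[sel] <- p$chrom
    res_a[sel] <- p$a[ai]
    res_b[sel] <- p$b[bidx]
  }
  tibble(chrom = res_chrom,
         start = pmin(res_a, res_b), end = pmax(res_a, res_b) + 1,
         pos_a = res_a, pos_b = res_b, distance = abs(res_b - res_a))
}
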