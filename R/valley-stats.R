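#' Paired signed-rank test of link rates versus matched-control rates
#'
#' Each link is paired with its matched control; the test is the two-sided
#' Wilcoxon signed-rank test on the paired differences (the paired analogue
#' of the Mann-Whitney rank test; a U test has no standard paired form, and
#' the design pairs each link with its own control). Zero differences are
#' dropped (the classical Wilcoxon convention) and `n_effective` reports
#' what remains. The null distribution is exact — by convolution over the
#' (possibly tied) ranks, equivalent to enumerating all 2^n sign
#' assignments — for `n_effective <= 25`, and a normal approximation with
#' tie correction and continuity correction beyond.
#'
#' @param observed,control Equal-length numeric vectors of paired rates.
#' @param exact_limit Largest `n_effective` using the exact null
#'   (default 25).
#' @return List: `statistic` (W, rank sum of positive differences),
#'   `statistic_centered` (W minus its null mean; antisymmetric under
#'   swapping the inputs), `p` (two-sided, in (0, 1\]), `n_effective`,
#'   `degenerate`, `method`.
#' @examples
#' paired_rank_test(1:5, 2:6)$p  # 2/32 = 0.0625
#' @export
paired_rank_test <- function(observed, control, exact_limit = 25) {
  if (length(observed) != length(control)) abort("paired vectors differ in length")
  if (length(observed) < 1) abort("need n >= 1 pairs")
  d <- observed - control
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, statistic_centered = NA_real_, p = 1,
                n_effective = 0L, degenerate = TRUE, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_limit) {
    # exact null over sign flips: distribution of the sum of a random subset
    # of the (doubled, hence integer) ranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)   # f[s + 1] = #assignments with doubled-sum s
    f[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), f[seq_len(total + 1 - rr)])
      f <- f + shifted
    }
    W2 <- as.integer(round(2 * W))
    p_le <- sum(f[seq_len(W2 + 1)]) / 2^n
    p_ge <- sum(f[(W2 + 1):(total + 1)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- max(min(1, 2 * stats::pnorm(-abs(z))), .Machine$double.xmin)
    method <- "normal_tie_corrected"
  }
  list(statistic = W, statistic_centered = W - mu, p = p,
       n_effective = n, degenerate = FALSE, method = method)
}

#' Permutation test of the median link rate against the pair universe
#'
#' Builds, per distance class, the null distribution of the median
#' recombination rate: each of `n_perm` rounds samples as many random
#' point pairs (same chromosome, distance in class) from the
#' `points_a` x `points_b` universe as there are links in the class and
#' records the median span rate. The observed median is ranked within this
#' null; the one-sided depletion p value is
#' `(1 + #\{null <= observed\}) / (1 + n_perm)`, so p is never 0 and the
#' smallest attainable value at 10,000 rounds is 1/10,001.
#'
#' @param links A link table.
#' @param map A [genetic_map()].
#' @param points_a,points_b Point tibbles (`chrom`, `pos`) spanning the
#'   null universe (e.g. genotyped SNPs and TSSs).
#' @param n_perm Permutation rounds (default 10000).
#' @return Tibble: `distance_class`, `n`, `observed_median`,
#'   `null_median_mean`, `null_median_sd`, `p_permutation`.
#' @export
permutation_median_test <- function(links, map, points_a, points_b,
                                    n_perm = 10000) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  rates <- interval_rate(map, link_spans(links))$rate
  purrr::map_dfr(c("SHORT", "MEDIUM", "LONG"), function(cl) {
    sel <- which(as.character(links$distance_class) == cl)
    if (length(sel) == 0) return(NULL)
    obs <- median(rates[sel])
    pairs <- sample_null_pairs(points_a, points_b, length(sel) * n_perm, cl)
    null_rates <- matrix(interval_rate(map, pairs)$rate, nrow = length(sel))
    null_med <- apply(null_rates, 2, median)
    tibble(distance_class = cl, n = length(sel), observed_median = obs,
           null_median_mean = mean(null_med), null_median_sd = sd(null_med),
           p_permutation = (1 + sum(null_med <= obs)) / (1 + n_perm))
  })
}

#' End-to-end recombination-rate valley test
#'
#' Per distance class, compares observed link-span rates with matched
#' random controls (paired signed-rank test) and with the null pair
#' universe (permutation test of the median), and flags classes where both
#' available p values fall below `alpha` (default 1e-4).
#'
#' @param links A link table.
#' @param map A [genetic_map()].
#' @param assembly A [genome_assembly()].
#' @param control_strategy `"length"`, `"rejection"`, `"kdtree"` or
#'   `"domain"`.
#' @param tracks Feature tracks (rejection strategy).
#' @param index Candidate index (kdtree strategy).
#' @param domains Domain intervals (domain strategy).
#' @param ctcf_motifs Optional motif intervals (kdtree strategy exclusion).
#' @param points_a,points_b Null pair universe; defaults: map marker
#'   positions, and link anchor-b midpoints, respectively. Set `n_perm = 0`
#'   to skip the permutation test.
#' @param n_perm Permutation rounds (default 10000).
#' @param alpha Significance threshold (default 1e-4).
#' @param include_unmatched Keep controls that failed to match within
#'   tolerance (default FALSE: their links drop from the paired test).
#' @return A `valley_test` object; see [tidy.valley_test()].
#' @export
valley_test <- function(links, map, assembly,
                        control_strategy = c("length", "rejection", "kdtree", "domain"),
                        tracks = NULL, index = NULL, domains = NULL,
                        ctcf_motifs = NULL, points_a = NULL, points_b = NULL,
                        n_perm = 10000, alpha = 1e-4,
                        include_unmatched = FALSE) {
  control_strategy <- match.arg(control_strategy)
  if (nrow(links) == 0) abort("no links")
  controls <- switch(control_strategy,
    length = sample_length_matched(links, assembly),
    rejection = sample_feature_matched_rejection(links, assembly, tracks),
    kdtree = {
      if (is.null(index)) abort("kdtree strategy needs a candidate index")
      sample_kdtree_matched(index, links, ctcf_motifs = ctcf_motifs)
    },
    domain = {
      if (is.null(domains)) abort("domain strategy needs domains")
      sample_within_domain(links, domains)
    })
  if (!include_unmatched) controls <- controls[controls$matched, ]
  obs_rate <- interval_rate(map, link_spans(links))$rate
  ctrl_rate <- rep(NA_real_, nrow(links))
  ctrl_rate[controls$link_id] <- interval_rate(map, controls)$rate
  perm <- if (n_perm > 0) {
    if (is.null(points_a)) points_a <- tibble(chrom = map$chrom, pos = map$pos)
    if (is.null(points_b)) {
      points_b <- dplyr::distinct(
        tibble(chrom = links$chrom,
               pos = floor((links$start_b + links$end_b) / 2)))
    }
    permutation_median_test(links, map, points_a, points_b, n_perm)
  }
  by_class <- purrr::map_dfr(c("SHORT", "MEDIUM", "LONG"), function(cl) {
    sel <- which(as.character(links$distance_class) == cl)
    if (length(sel) == 0) return(NULL)
    paired_sel <- sel[!is.na(ctrl_rate[sel])]
    pr <- if (length(paired_sel) > 0) {
      paired_rank_test(obs_rate[paired_sel], ctrl_rate[paired_sel])
    } else {
      list(statistic = NA_real_, p = NA_real_, n_effective = 0L)
    }
    p_perm <- if (!is.null(perm) && cl %in% perm$distance_class) {
      perm$p_permutation[perm$distance_class == cl]
    } else NA_real_
    ps <- c(pr$p, p_perm)
    tibble(distance_class = cl, n = length(sel), n_paired = length(paired_sel),
           mean_observed = mean(obs_rate[sel]),
           median_observed = median(obs_rate[sel]),
           mean_control = mean(ctrl_rate[paired_sel]),
           median_control = median(ctrl_rate[paired_sel]),
           statistic = pr$statistic, p_paired = pr$p,
           n_effective = pr$n_effective, p_permutation = p_perm,
           significant = all(is.na(ps) == FALSE & ps < alpha) && length(ps[!is.na(ps)]) > 0)
  })
  structure(list(
    by_class = by_class,
    null_summary = perm,
    controls = controls,
    config = list(control_strategy = control_strategy, n_perm = n_perm,
                  alpha = alpha, include_unmatched = include_unmatched,
                  paired_test = "wilcoxon_signed_rank_two_sided",
                  permutation_side = "one_sided_depletion")),
    class = "valley_test")
}

#' @export
print.valley_test <- function(x, ...) {
  cat("Recombination-rate valley test (", x$config$control_strategy,
      "-matched controls, ", x$config$n_perm, " permutations)\n", sep = "")
  print(as.data.frame(x$by_class), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a valley test
#'
#' @param x A `valley_test` object.
#' @param ... Unused.
#' @return The per-distance-class result tibble.
#' @export
tidy.valley_test <- function(x, ...) x$by_class

#' @rdname tidy.valley_test
#' @export
glance.valley_test <- function(x, ...) {
  tibble(n_links = sum(x$by_class$n),
         n_classes = nrow(x$by_class),
         n_significant = sum(x$by_class$significant),
         control_strategy = x$config$control_strategy,
         n_perm = x$config$n_perm,
         alpha = x$config$alpha)
}

#' Compare valley depth between two link groups
#'
#' Depletion per group is mean(control rate) - mean(observed rate) over
#' paired links with length-matched controls; the between-group difference
#' is tested by permuting group labels over the per-link depletion values.
#'
#' @param links_a,links_b Link tables (e.g. housekeeping vs other targets).
#' @param map A [genetic_map()].
#' @param assembly A [genome_assembly()].
#' @param n_perm_labels Label permutations (default 10000).
#' @return List: `depletion_a`, `depletion_b`, `delta`
#'   (`depletion_a - depletion_b`), `p` (two-sided label-permutation p).
#' @export
group_compare <- function(links_a, links_b, map, assembly,
                          n_perm_labels = 10000) {
  if (nrow(links_a) == 0 || nrow(links_b) == 0) abort("both groups must be non-empty")
  dep <- function(l) {
    ctrl <- sample_length_matched(l, assembly)
    interval_rate(map, ctrl)$rate - interval_rate(map, link_spans(l))$rate
  }
  da <- dep(links_a); db <- dep(links_b)
  delta <- mean(da) - mean(db)
  pooled <- c(da, db)
  na <- length(da)
  perm_delta <- vapply(seq_len(n_perm_labels), function(i) {
    lab <- sample.int(length(pooled), na)
    mean(pooled[lab]) - mean(pooled[-lab])
  }, numeric(1))
  p <- (1 + sum(abs(perm_delta) >= abs(delta))) / (1 + n_perm_labels)
  list(depletion_a = mean(da), depletion_b = mean(db), delta = delta, p = p,
       n_a = na, n_b = length(db))
}
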