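# Matched-control generators and the null-pair sampler.

test_that("length-matched controls have exact length and uniform starts", {
  a <- genome_assembly("chr1", 1e7)
  l <- point_links("chr1", 5e6, 5e6 + 1e5 - 1)  # span exactly 100 kb
  set.seed(21)
  reps <- purrr::map_dfr(1:2000, function(i) sample_length_matched(l, a))
  expect_true(all(reps$end - reps$start == 1e5))
  expect_true(all(reps$chrom == "chr1"))
  expect_true(all(reps$start >= 0 & reps$end <= 1e7))
  ks <- suppressWarnings(stats::ks.test(reps$start / (1e7 - 1e5), "punif"))
  expect_gt(ks$p.value, 0.01)
  # chromosome length equal to span length forces [0, L)
  a2 <- genome_assembly("chr1", 99999)
  forced <- sample_length_matched(point_links("chr1", 0, 1e5 - 2), a2)
  expect_equal(forced$start, 0)
  expect_equal(forced$end, 99999)
})

test_that("rejection sampler accepts immediately on constant tracks", {
  a <- tiny_assembly()
  trks <- list(constant_track(a, 0.5, "gc"), constant_track(a, 0.01, "cpg"))
  l <- point_links("chr1", 2e5, 3e5)
  set.seed(2)
  ctrl <- sample_feature_matched_rejection(l, a, trks)
  expect_equal(ctrl$iterations, 1L)
  expect_equal(ctrl$feature_distance, 0)
  expect_true(ctrl$matched)
})

test_that("rejection sampler finds an engineered matching window", {
  # one feature stepping along the chromosome; only one 10-kb window carries
  # the link's value, so accepted controls must land there
  a <- genome_assembly("chr1", 1e6)
  n_bin <- 1000
  v <- rep(0.2, n_bin)
  v[501:510] <- 0.8   # target window [500kb, 510kb)
  v[101:110] <- 0.8   # the link's own location [100kb, 110kb)
  tr <- feature_track(tibble::tibble(chrom = "chr1",
                                     start = (seq_len(n_bin) - 1) * 1000,
                                     value = v), feature_name = "gc")
  l <- point_links("chr1", 1e5, 1.1e5 - 2)  # span = [100kb, 110kb)
  set.seed(31)
  hits <- purrr::map_dfr(1:100, function(i)
    sample_feature_matched_rejection(l, a, list(tr), tolerance = 0.01))
  expect_true(all(hits$matched))
  in_either <- (hits$start >= 4.99e5 & hits$end <= 5.11e5) |
    (hits$start >= 0.99e5 & hits$end <= 1.11e5)
  expect_true(all(in_either))
})

test_that("rejection sampler exhausts at tolerance zero and flags best-so-far", {
  a <- tiny_assembly()
  scn <- small_scenario()
  tr <- scn$tracks$gc
  l <- point_links("chr1", 2e5, 3e5)
  set.seed(4)
  ctrl <- sample_feature_matched_rejection(l, scn$assembly, list(tr),
                                           tolerance = 0, max_iter = 500)
  expect_false(ctrl$matched)
  expect_equal(ctrl$iterations, 500L)
  expect_true(is.finite(ctrl$feature_distance))
  # no tracks at all degrades to length matching with a warning
  expect_warning(
    deg <- sample_feature_matched_rejection(l, scn$assembly, list()),
    "length matching")
  expect_equal(deg$end - deg$start, 1e5 + 1)
})

test_that("acceptance rate is monotone in tolerance on a fixed landscape", {
  scn <- small_scenario()
  l <- scn$links[1:30, ]
  rates <- vapply(c(0.002, 0.01, 0.05), function(tol) {
    set.seed(77)
    mean(sample_feature_matched_rejection(l, scn$assembly, scn$tracks,
                                          tolerance = tol,
                                          max_iter = 300)$matched)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("candidate enumeration respects bounds and count arithmetic", {
  a <- genome_assembly("chr1", 1e6)
  trks <- list(constant_track(a, 0.5, "gc"))
  idx <- build_candidate_index(a, trks, grid = 1000,
                               length_range = c(1000, 1e5), length_step = 1000)
  iv <- idx$per_chrom$chr1$intervals
  expect_lte(nrow(iv), 1e5)
  expect_true(all(iv$start >= 0 & iv$end <= 1e6))
  expect_true(all((iv$end - iv$start) %in% seq(1000, 1e5, 1000)))
  # memory guard names the cap
  expect_error(build_candidate_index(a, trks, grid = 10,
                                     length_range = c(1000, 1e6),
                                     length_step = 10, max_candidates = 1e5),
               "max_candidates")
})

test_that("k-d tree nearest neighbours equal a brute-force scan", {
  set.seed(12)
  scn <- small_scenario()
  idx <- build_candidate_index(scn$assembly, scn$tracks, grid = 25000,
                               length_range = c(5e4, 5e5), length_step = 25000)
  pc <- idx$per_chrom$chr1
  expect_lte(nrow(pc$feats), 1e4)
  q <- matrix(runif(20 * ncol(pc$feats)), 20)
  res <- recvalley:::kdtree_query(pc$tree, q, 15)
  for (i in 1:20) {
    want <- oracle_knn(pc$feats, q[i, ], 15)
    # compare distances, not indices, so exact ties cannot flake
    d_want <- sqrt(colSums((t(pc$feats[want, ]) - q[i, ])^2))
    expect_equal(res$dist[i, ], d_want, tolerance = 1e-12)
  }
  # k beyond the candidate count saturates to all candidates
  sat <- recvalley:::kdtree_query(pc$tree, q[1, , drop = FALSE],
                                  nrow(pc$feats) + 500)
  expect_equal(ncol(sat$idx), nrow(pc$feats))
  expect_equal(sort(sat$idx[1, ]), seq_len(nrow(pc$feats)))
})

test_that("k-d tree matching filters self-overlap and CTCF candidates", {
  scn <- small_scenario()
  idx <- build_candidate_index(scn$assembly, scn$tracks, grid = 10000,
                               length_range = c(1e4, 5e5), length_step = 10000)
  l <- scn$links[1:20, ]
  set.seed(9)
  ctrl <- sample_kdtree_matched(idx, l, k = 200)
  # never the link span itself, never > 50% overlap of the shorter interval
  for (j in seq_len(nrow(ctrl))) {
    li <- l[ctrl$link_id[j], ]
    ov <- max(0, min(ctrl$end[j], li$span_end) - max(ctrl$start[j], li$span_start))
    shorter <- min(ctrl$end[j] - ctrl$start[j], li$span_end - li$span_start)
    expect_lte(ov / shorter, 0.5)
    gap <- max(0, max(ctrl$start[j] - li$span_end, li$span_start - ctrl$end[j]))
    if (ov == 0) expect_gte(gap, 1000)
  }
  expect_true(all(ctrl$chrom == l$chrom[ctrl$link_id]))
  # with motifs supplied, no control overlaps a motif
  set.seed(10)
  ctrl2 <- sample_kdtree_matched(idx, l, k = 200, ctcf_motifs = scn$ctcf_motifs)
  ov <- recvalley:::intervals_overlap_any(
    tibble::tibble(chrom = ctrl2$chrom, start = ctrl2$start, end = ctrl2$end),
    scn$ctcf_motifs)
  expect_false(any(ov))
})

test_that("50 percent overlap rule measured against the shorter interval", {
  cand <- tibble::tibble(chrom = "chr1",
                         start = c(0, 0), end = c(1e5, 1e5))
  # span [40kb, 140kb): candidate shares 60 kb of its 100 kb -> filtered;
  # span [60kb, 160kb): shares 40 kb -> eligible
  p60 <- recvalley:::candidate_proximity(cand[1, ], 4e4, 1.4e5)
  p40 <- recvalley:::candidate_proximity(cand[2, ], 6e4, 1.6e5)
  expect_gt(p60$overlap_frac, 0.5)
  expect_lte(p40$overlap_frac, 0.5)
})

test_that("domain-constrained controls stay inside the source domain", {
  dom <- tibble::tibble(chrom = "chr1", start = c(1e5, 8e5), end = c(4e5, 9e5))
  l <- point_links("chr1", 1.5e5, 2.5e5)
  set.seed(13)
  reps <- purrr::map_dfr(1:1000, function(i) sample_within_domain(l, dom))
  expect_true(all(reps$start >= 1e5 & reps$end <= 4e5))
  expect_true(all(reps$end - reps$start == 1e5 + 1))
  # uniform over the feasible start range
  ks <- suppressWarnings(
    stats::ks.test((reps$start - 1e5) / (3e5 - (1e5 + 1)), "punif"))
  expect_gt(ks$p.value, 0.01)
  # domain exactly the span length is forced; uncontained links are skipped
  dom2 <- tibble::tibble(chrom = "chr1", start = 1.5e5, end = 2.5e5 + 1)
  forced <- sample_within_domain(l, dom2)
  expect_equal(forced$start, 1.5e5)
  l_out <- point_links("chr1", 5e5, 6e5)
  expect_warning(res <- sample_within_domain(l_out, dom), "no domain")
  expect_equal(nrow(res), 0)
})

test_that("null pairs respect the distance class and sample uniformly", {
  # small enumerable universe: 20 SNPs x 5 TSS
  set.seed(17)
  snps <- tibble::tibble(chrom = "chr1", pos = sort(sample(0:3e5, 20)))
  tss <- tibble::tibble(chrom = "chr1", pos = sort(sample(0:3e5, 5)))
  uni <- tidyr::expand_grid(a = snps$pos, b = tss$pos) |>
    dplyr::filter(abs(b - a) >= 1e4, abs(b - a) <= 1e5 - 1)
  draws <- sample_null_pairs(snps, tss, 50000, "MEDIUM")
  expect_true(all(draws$distance >= 1e4 & draws$distance < 1e5))
  expect_true(all(draws$end - draws$start - 1 == draws$distance))
  got <- table(paste(draws$pos_a, draws$pos_b))
  expect_equal(sort(names(got)), sort(paste(uni$a, uni$b)))
  chi <- stats::chisq.test(as.numeric(got))
  expect_gt(chi$p.value, 0.01)
  # a single feasible pair is always returned
  one <- sample_null_pairs(tibble::tibble(chrom = "chr1", pos = 0),
                           tibble::tibble(chrom = "chr1", pos = 5e4),
                           10, "MEDIUM")
  expect_true(all(one$pos_b == 5e4))
  expect_error(sample_null_pairs(tibble::tibble(chrom = "chr1", pos = 0),
                                 tibble::tibble(chrom = "chr1", pos = 100),
                                 1, "LONG"),
               "LONG")
})
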