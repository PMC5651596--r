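# Link-set hygiene: CTCF interruption, best-per-target, pruning,
# thresholding, shifting, constitutive classification, activity links.

test_that("CTCF interruption requires full motif containment in the gap", {
  l <- as_links(tibble::tibble(chrom = "chr1", start_a = 1000, end_a = 1200,
                               start_b = 9000, end_b = 9200))
  none <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  expect_equal(nrow(filter_ctcf_uninterrupted(l, none)$uninterrupted), 1)

  gap_motif <- tibble::tibble(chrom = "chr1", start = 5000, end = 5019)
  res <- filter_ctcf_uninterrupted(l, gap_motif)
  expect_equal(nrow(res$interrupted), 1)
  expect_equal(nrow(res$uninterrupted), 0)

  # motif overlapping anchor_a does not interrupt
  on_anchor <- tibble::tibble(chrom = "chr1", start = 1190, end = 1209)
  expect_equal(nrow(filter_ctcf_uninterrupted(l, on_anchor)$uninterrupted), 1)

  # idempotence: filtering the uninterrupted set again changes nothing
  scn <- small_scenario()
  once <- filter_ctcf_uninterrupted(scn$links, scn$ctcf_motifs)
  twice <- filter_ctcf_uninterrupted(once$uninterrupted, scn$ctcf_motifs)
  expect_equal(nrow(twice$uninterrupted), nrow(once$uninterrupted))
  expect_equal(nrow(once$uninterrupted) + nrow(once$interrupted), nrow(scn$links))
})

test_that("best-per-target keeps the minimum p with deterministic ties", {
  l <- point_links("chr1", c(1e4, 2e4, 5e4, 8e4), c(6e4, 6e4, 9e4, 120e3),
                   score = c(1e-8, 1e-5, 1e-3, 1e-3),
                   target_id = c("G1", "G1", "G2", "G2"))
  best <- select_best_per_target(l)
  expect_equal(nrow(best), 2)
  expect_equal(best$score[best$target_id == "G1"], 1e-8)
  # G2 tie at 1e-3: shorter distance wins (5e4->9e4 is 4e4 < 8e4->120e3)
  expect_equal(best$start_a[best$target_id == "G2"], 5e4)
  # single link per target passes through unchanged
  expect_equal(nrow(select_best_per_target(best)), 2)
  # missing target dropped with warning
  l2 <- l
  l2$target_id[1] <- NA
  expect_warning(select_best_per_target(l2), "without target_id")
})

test_that("pruning is greedy by significance with anchor exclusion", {
  # two links share the 1e4 SNP anchor: only the more significant survives
  l <- point_links("chr1", c(1e4, 1e4, 2e5), c(6e4, 9e4, 4e5),
                   score = c(1e-9, 1e-4, 1e-6),
                   target_id = c("A", "B", "C"))
  pruned <- prune_overlapping(l, exclusion_radius = 1000)
  expect_equal(sort(pruned$target_id), c("A", "C"))
  # spatially disjoint links are all retained
  l2 <- point_links("chr1", c(1e4, 1e5, 5e5), c(6e4, 1.8e5, 8e5),
                    score = c(0.1, 0.2, 0.3))
  expect_equal(nrow(prune_overlapping(l2, 1000)), 3)
  # postcondition: no two accepted anchors within the radius; idempotent
  scn <- small_scenario()
  p1 <- prune_overlapping(scn$links, 1000)
  mids <- sort(c((p1$start_a + p1$end_a) / 2, (p1$start_b + p1$end_b) / 2))
  by_chrom <- split(c((p1$start_a + p1$end_a) / 2, (p1$start_b + p1$end_b) / 2),
                    rep(p1$chrom, 2))
  expect_true(all(vapply(by_chrom, function(v) all(diff(sort(v)) > 1000),
                         logical(1))))
  expect_equal(nrow(prune_overlapping(p1, 1000)), nrow(p1))
})

test_that("thresholding selects by fraction or p cutoff and is idempotent", {
  l <- point_links("chr1", seq(1e4, 1e5, 1e4), seq(1e4, 1e5, 1e4) + 5e4,
                   score = (1:10) / 10)
  expect_equal(nrow(threshold_links(l, "top_fraction", 1.0)), 10)
  top2 <- threshold_links(l, "top_fraction", 0.2)
  expect_equal(sort(top2$score), c(0.9, 1.0))
  expect_equal(threshold_links(top2, "top_fraction", 1.0), top2)
  expect_error(threshold_links(l, "top_fraction", 0), "\\(0, 1\\]")
  expect_error(threshold_links(l, "top_fraction", 1.5), "\\(0, 1\\]")
  expect_equal(nrow(threshold_links(l, "max_p", 0.05)), 0)
  expect_equal(nrow(threshold_links(l, "max_p", 0.35)), 3)
})

test_that("shifting preserves length and stays within the chromosome", {
  scn <- small_scenario()
  expect_error(shift_links(scn$links, scn$assembly, min_shift = 0),
               "min_shift")
  set.seed(8)
  sh <- shift_links(scn$links, scn$assembly)
  expect_equal(sh$span_end - sh$span_start,
               scn$links$span_end - scn$links$span_start)
  expect_true(all(sh$span_start >= 0))
  expect_true(all(sh$span_end <= 5e6))
  # links sit in planted valleys, so a local shift moves mass out of the
  # valley: shifted spans should not have a lower mean rate
  obs <- interval_rate(scn$map, tibble::tibble(
    chrom = scn$links$chrom, start = scn$links$span_start,
    end = scn$links$span_end))$rate
  shifted <- interval_rate(scn$map, tibble::tibble(
    chrom = sh$chrom, start = sh$span_start, end = sh$span_end))$rate
  expect_gte(mean(shifted), mean(obs))
})

test_that("constitutive classification honours the anchor tolerance", {
  a <- point_links("chr1", 1e4, 6e4)
  b_near <- point_links("chr1", 1e4 + 500, 6e4 + 500)   # within 1 kb
  b_far <- point_links("chr1", 3e5, 5e5)
  res <- classify_constitutive(list(t1 = a, t2 = dplyr::bind_rows(b_near, b_far)),
                               min_tissues = 2, anchor_tolerance = 1000)
  expect_equal(nrow(res$constitutive), 2)   # a and b_near match each other
  expect_equal(nrow(res$specific), 1)       # b_far is tissue-specific
  expect_equal(nrow(res$constitutive) + nrow(res$specific), 3)
  # identical link in all sets is constitutive at min_tissues = n
  res2 <- classify_constitutive(list(x = a, y = a, z = a), min_tissues = 3)
  expect_equal(nrow(res2$specific), 0)
  expect_error(classify_constitutive(list(a)), ">= 2")
})

test_that("activity links come from correlation over cell types", {
  peaks <- tibble::tibble(chrom = "chr1", start = c(1e4, 5e4),
                          end = c(1e4, 5e4) + 200, peak_id = c("p1", "p2"))
  sig <- matrix(c(1, 2, 3, 4, 5,
                  2, 2, 2, 2, 2), nrow = 2, byrow = TRUE,
                dimnames = list(c("p1", "p2"), NULL))
  expr <- matrix(3 + 2 * c(1, 2, 3, 4, 5), nrow = 1,
                 dimnames = list("G1", NULL))
  tss <- tibble::tibble(chrom = "chr1", pos = 2e4, gene = "G1")
  # p1 is an exact affine transform: r = 1; p2 is constant: skipped
  expect_warning(
    l <- predict_activity_links(peaks, sig, expr, tss, max_distance = 1e6,
                                r_threshold = 0.99),
    "zero-variance")
  expect_equal(nrow(l), 1)
  expect_equal(l$score, 1)
  expect_equal(l$target_id, "G1")
  # peak 2 Mb away is never tested
  tss_far <- tibble::tibble(chrom = "chr1", pos = 2.01e6 + 1e4, gene = "G1")
  sig1 <- sig[1, , drop = FALSE]
  l2 <- predict_activity_links(peaks[1, ], sig1, expr, tss_far,
                               max_distance = 1e6, r_threshold = -1)
  expect_equal(nrow(l2), 0)
  # independent noise almost never clears r >= 0.99 with 5 cell types
  set.seed(10)
  npk <- 40
  peaks_n <- tibble::tibble(chrom = "chr1", start = seq(1e4, 4e5, length.out = npk),
                            end = seq(1e4, 4e5, length.out = npk) + 200,
                            peak_id = paste0("n", seq_len(npk)))
  sig_n <- matrix(rnorm(npk * 5), npk,
                  dimnames = list(peaks_n$peak_id, NULL))
  expr_n <- matrix(rnorm(5), 1, dimnames = list("G1", NULL))
  l3 <- predict_activity_links(peaks_n, sig_n, expr_n, tss,
                               max_distance = 1e6, r_threshold = 0.99)
  expect_equal(nrow(l3), 0)
})
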