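# Methylation correlation analyses and the rate predictor.

test_that("window correlation is exact on constructed signals", {
  a <- genome_assembly("chr1", 4e5)
  mk <- function(vals) feature_track(
    tibble::tibble(chrom = "chr1", start = seq(0, 3.75e5, 25000), value = vals),
    bin_size = 25000)
  set.seed(2)
  x <- rnorm(16)
  tx <- mk(x)
  expect_equal(window_correlation(tx, tx, a, window = 1e5)$r, 1)
  expect_equal(window_correlation(tx, mk(-x), a, window = 1e5)$r, -1)
  # symmetry
  ty <- mk(rnorm(16))
  expect_equal(window_correlation(tx, ty, a, window = 1e5)$r,
               window_correlation(ty, tx, a, window = 1e5)$r)
  # hand-computed Pearson on 4 window means: bins constant per 100-kb window
  tx4 <- mk(rep(c(1, 2, 3, 4), each = 4))
  ty4 <- mk(rep(c(2, 1, 4, 3), each = 4))
  res <- window_correlation(tx4, ty4, a, window = 1e5)
  expect_equal(res$r, 0.6, tolerance = 1e-12)
  expect_equal(res$n_windows, 4)
  expect_error(window_correlation(tx, ty, a, window = 4e5), "3 informative")
})

test_that("window correlation spans track, methylation and map signals", {
  scn <- small_scenario()
  wc <- window_correlation(scn$methylation, scn$map, scn$assembly,
                           window = 2.5e5)
  expect_true(wc$r < 0)  # generator couples methylation negatively to rate
  expect_true(wc$n_windows > 10)
  sp <- window_correlation(scn$methylation, scn$map, scn$assembly,
                           window = 2.5e5, method = "spearman")
  expect_true(sp$r < 0)
})

test_that("methylation quantile profile bins links and tracks coupling", {
  scn <- small_scenario()
  qp <- quantile_rate_profile(scn$links, scn$methylation, scn$map,
                              n_quantiles = 5)
  expect_equal(sum(qp$n), nrow(scn$links))  # partition (all spans have CpGs)
  expect_true(all(diff(qp$meth_lo) > 0))
  expect_error(quantile_rate_profile(scn$links[1:3, ], scn$methylation,
                                     scn$map, n_quantiles = 5), "fewer links")

  # deterministic monotone coupling rate = 2 - methylation: strictly
  # decreasing per-quantile means
  a <- genome_assembly("chr1", 2e6)
  pos <- seq(100, 2e6 - 100, by = 100)
  level <- rep(seq(0.05, 0.95, length.out = 40), each = ceiling(length(pos) / 40))[seq_along(pos)]
  meth <- methylation_track(tibble::tibble(chrom = "chr1", pos = pos, level = level))
  # map whose rate at x equals 2 - level(x)
  mpos <- seq(0, 2e6, by = 100)
  lvl_at <- level[pmin(pmax(findInterval(mpos, pos), 1), length(level))]
  m <- genetic_map(tibble::tibble(chrom = "chr1", pos = mpos,
                                  cum_cm = cumsum(c(0, (2 - lvl_at[-1]) * 100 / 1e6))))
  starts <- seq(1e4, 1.8e6, length.out = 60)
  l <- point_links("chr1", starts, starts + 3e4)
  qp2 <- quantile_rate_profile(l, meth, m, n_quantiles = 6)
  expect_true(all(diff(qp2$mean_rate) < 0))

  # all-identical methylation collapses into a single occupied bin
  meth_const <- methylation_track(tibble::tibble(chrom = "chr1", pos = pos,
                                                 level = 0.5))
  qp3 <- quantile_rate_profile(l, meth_const, m, n_quantiles = 6)
  expect_equal(nrow(qp3), 1)
  expect_equal(qp3$quantile, 1)  # ties land in the lowest quantile
  expect_equal(qp3$n, 60)
})

test_that("feature table reports coverage fractions and methylation", {
  iv <- tibble::tibble(chrom = "chr1", start = c(1e5, 3e5, 6e5),
                       end = c(2e5, 4e5, 7e5))
  # link spans: one covering the first interval entirely, one covering half
  # of the second, none near the third
  l <- point_links("chr1", c(5e4, 3e5), c(2.5e5, 3.5e5 - 1))
  ft <- interval_feature_table(iv, list(eQTL = l))
  expect_equal(ft$frac_eQTL, c(1, 0.5, 0))
  expect_equal(ft$length, rep(1e5, 3))
  # methylation means and the missing flag
  meth <- methylation_track(tibble::tibble(chrom = "chr1",
                                           pos = c(1.2e5, 1.4e5), level = c(0.2, 0.6)))
  ft2 <- interval_feature_table(iv, list(eQTL = l), methylation = meth)
  expect_equal(ft2$methylation[1], 0.4)
  expect_true(all(ft2$meth_missing[2:3]))
})

test_that("predictor recovers deterministic signal and not noise", {
  set.seed(50)
  n <- 600
  chrom <- sample(paste0("chr", 1:6), n, replace = TRUE)
  meth <- runif(n)
  feats <- tibble::tibble(chrom = chrom, length = runif(n, 1e4, 1e6),
                          methylation = meth)
  rates <- 2 - 1.5 * meth          # rate a deterministic function
  fit <- train_rate_predictor(feats, rates, cv_folds = 5, num_trees = 150)
  expect_gte(fit$cv_pearson, 0.9)
  # pure-noise features carry no skill
  feats_n <- tibble::tibble(chrom = chrom, length = runif(n, 1e4, 1e6),
                            methylation = runif(n))
  rates_n <- rnorm(n)
  fit_n <- train_rate_predictor(feats_n, rates_n, cv_folds = 5, num_trees = 150)
  expect_lt(abs(fit_n$cv_pearson), 0.1)
  # identical seeds give identical skill
  set.seed(51)
  f1 <- train_rate_predictor(feats, rates, num_trees = 50)
  set.seed(51)
  f2 <- train_rate_predictor(feats, rates, num_trees = 50)
  expect_identical(f1$cv_pearson, f2$cv_pearson)
  expect_identical(f1$oof_predictions, f2$oof_predictions)
  # constant target: undefined correlation flag, MSE still reported
  fit_c <- suppressWarnings(  # forest warns on a constant response
    train_rate_predictor(feats, rep(1.5, n), num_trees = 50))
  expect_true(is.na(fit_c$cv_pearson))
  expect_true(is.finite(fit_c$cv_mse))
  expect_error(train_rate_predictor(feats[1:10, ], rates[1:10]), ">= 50")
})

test_that("depletion recapitulation is 1 for an oracle and 0 for a constant", {
  set.seed(52)
  n <- 200
  link_feats <- tibble::tibble(methylation = runif(n, 0.6, 1))
  ctrl_feats <- tibble::tibble(methylation = runif(n, 0, 0.4))
  true_rate <- function(f) 2 - 1.5 * f$methylation
  train <- dplyr::bind_rows(link_feats, ctrl_feats)
  fit <- train_rate_predictor(train, true_rate(train), num_trees = 200)
  res <- depletion_recapitulation(fit, link_feats, ctrl_feats,
                                  true_rate(link_feats), true_rate(ctrl_feats))
  expect_gt(res$fraction, 0.8)   # near-oracle model recaptures the depth
  expect_false(res$undefined)
  # constant predictor: trained on a constant target, predicts no difference
  fit0 <- suppressWarnings(  # forest warns on a constant response
    train_rate_predictor(train, rep(1, 2 * n), num_trees = 50))
  res0 <- depletion_recapitulation(fit0, link_feats, ctrl_feats,
                                   true_rate(link_feats), true_rate(ctrl_feats))
  expect_equal(res0$fraction, 0, tolerance = 1e-9)
  # zero observed difference flags undefined
  resU <- depletion_recapitulation(fit, link_feats, ctrl_feats,
                                   rep(1, n), rep(1, n))
  expect_true(resU$undefined)
})
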