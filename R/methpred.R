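#' Genome-scan correlation between two signals
#'
#' Tiles the genome with non-overlapping windows (default 500 kb), takes the
#' per-window mean of each signal, drops windows missing either, and
#' correlates across windows. Accepts any pair of objects with a
#' [window_means()] method ([feature_track()], [methylation_track()],
#' [genetic_map()]).
#'
#' @param track_x,track_y Signal objects.
#' @param assembly A [genome_assembly()].
#' @param window Window size in bp (default 5e5).
#' @param method `"pearson"` or `"spearman"`.
#' @return List: `r`, `p`, `n_windows`, `method`, `window`.
#' @export
window_correlation <- function(track_x, track_y, assembly, window = 5e5,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (window < 1) abort("window must be >= 1 bp")
  wx <- window_means(track_x, assembly, window)
  wy <- window_means(track_y, assembly, window)
  ok <- !is.na(wx$mean_value) & !is.na(wy$mean_value)
  if (sum(ok) < 3) abort("fewer than 3 informative windows")
  ct <- stats::cor.test(wx$mean_value[ok], wy$mean_value[ok], method = method,
                        exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n_windows = sum(ok),
       method = method, window = window)
}

#' Mean recombination rate by methylation quantile
#'
#' Each link's methylation is the unweighted mean CpG level over its span
#' (links spanning no CpG are dropped); links are then binned into
#' methylation quantiles and the per-quantile mean and sd of the span
#' recombination rate reported. Tied methylation values land in the lowest
#' applicable quantile.
#'
#' @param links A link table.
#' @param methylation A [methylation_track()].
#' @param map A [genetic_map()].
#' @param n_quantiles Number of quantile bins (default 10).
#' @return Tibble classed `quantile_rate_profile`: `quantile`, `meth_lo`,
#'   `meth_hi`, `n`, `mean_rate`, `sd_rate`.
#' @export
quantile_rate_profile <- function(links, methylation, map, n_quantiles = 10) {
  if (n_quantiles < 2) abort("n_quantiles must be >= 2")
  meth <- methylation_interval_means(methylation, link_spans(links))
  keep <- !is.na(meth)
  links <- links[keep, ]; meth <- meth[keep]
  if (nrow(links) < n_quantiles) abort("fewer links with CpG coverage than quantiles")
  rate <- interval_rate(map, link_spans(links))$rate
  breaks <- quantile(meth, probs = seq(0, 1, length.out = n_quantiles + 1))
  ub <- unique(breaks)
  if (length(ub) == 1) {
    qid <- rep(1L, length(meth))  # all levels identical: one occupied bin
  } else {
    # map each collapsed interval back to the lowest quantile it covers
    qid_of_bin <- match(ub[-length(ub)], breaks)
    bin <- findInterval(meth, ub, all.inside = TRUE)
    qid <- qid_of_bin[bin]
  }
  out <- purrr::map_dfr(sort(unique(qid)), function(q) {
    sel <- qid == q
    tibble(quantile = q, meth_lo = min(meth[sel]), meth_hi = max(meth[sel]),
           n = sum(sel), mean_rate = mean(rate[sel]),
           sd_rate = if (sum(sel) > 1) sd(rate[sel]) else 0)
  })
  new_tibble_class(out, "quantile_rate_profile")
}

#' Per-interval feature table for rate prediction
#'
#' One row per interval with the predictor features: chromosome (categorical
#' adjustment), interval length in bp (the genomic-distance adjustment), the
#' fraction of the interval covered by each link type's merged spans, and
#' the mean methylation level (`NA` when the interval spans no CpG, with a
#' companion `meth_missing` indicator).
#'
#' @param intervals Interval tibble.
#' @param linksets_by_type Named list of link tables (names become feature
#'   columns `frac_<name>`).
#' @param methylation Optional [methylation_track()].
#' @param hotspots Optional hotspot intervals; adds `hotspot_density`
#'   (per kb).
#' @return A tibble, one row per interval.
#' @export
interval_feature_table <- function(intervals, linksets_by_type,
                                   methylation = NULL, hotspots = NULL) {
  intervals <- validate_intervals(intervals)
  out <- tibble(chrom = factor(intervals$chrom),
                length = intervals$end - intervals$start)
  for (nm in names(linksets_by_type)) {
    spans <- link_spans(linksets_by_type[[nm]])
    out[[paste0("frac_", nm)]] <-
      interval_coverage_bp(intervals, spans) / out$length
  }
  if (!is.null(methylation)) {
    m <- methylation_interval_means(methylation, intervals)
    out$methylation <- ifelse(is.na(m), 0, m)
    out$meth_missing <- is.na(m)
  }
  if (!is.null(hotspots)) {
    out$hotspot_density <- hotspot_density(intervals, hotspots)
  }
  out
}

#' Random-forest recombination-rate predictor with cross-validated skill
#'
#' Fits a random forest regression (500 trees) of interval recombination
#' rate on the feature table, evaluated by chromosome-stratified k-fold
#' cross-validation: folds are assigned round-robin over chromosomes (plain
#' row folds when chromosomes are fewer than folds), and skill is the
#' Pearson correlation and MSE of pooled out-of-fold predictions. The final
#' model is refit on all rows. Fully deterministic for a fixed RNG state.
#'
#' @param features Feature tibble (e.g. [interval_feature_table()]); a
#'   `chrom` column drives stratification and enters the model as a factor.
#' @param rates Numeric response (cM/Mb), one per row.
#' @param cv_folds Folds (default 5).
#' @param num_trees Trees (default 500).
#' @param min_rows Minimum rows required (default 50).
#' @param ... Further arguments to [randomForest::randomForest()] (e.g.
#'   `nodesize`, `mtry`).
#' @return List classed `rate_predictor`: `model` (randomForest),
#'   `cv_pearson`, `cv_mse`, `oof_predictions`, `folds`, `n`.
#' @export
train_rate_predictor <- function(features, rates, cv_folds = 5,
                                 num_trees = 500, min_rows = 50, ...) {
  features <- as.data.frame(features)
  features$meth_missing <- NULL
  if (nrow(features) < min_rows) abort(paste0("need >= ", min_rows, " rows"))
  if (cv_folds < 2) abort("cv_folds must be >= 2")
  if ("chrom" %in% names(features)) features$chrom <- factor(features$chrom)
  n <- nrow(features)
  fold <- if ("chrom" %in% names(features) &&
              length(unique(features$chrom)) >= cv_folds) {
    chroms <- sort(unique(as.character(features$chrom)))
    setNames(rep_len(seq_len(cv_folds), length(chroms)), chroms)[
      as.character(features$chrom)]
  } else {
    rep_len(seq_len(cv_folds), n)[sample.int(n)]
  }
  oof <- rep(NA_real_, n)
  for (k in seq_len(cv_folds)) {
    tr <- fold != k
    if (!any(tr) || all(tr)) next
    fit <- randomForest::randomForest(x = features[tr, , drop = FALSE],
                                      y = rates[tr], ntree = num_trees, ...)
    oof[!tr] <- predict(fit, features[!tr, , drop = FALSE])
  }
  ok <- !is.na(oof)
  cv_pearson <- if (sd(rates[ok]) == 0 || sd(oof[ok]) == 0) {
    NA_real_  # undefined for a constant target or constant prediction
  } else {
    cor(oof[ok], rates[ok])
  }
  cv_mse <- mean((oof[ok] - rates[ok])^2)
  model <- randomForest::randomForest(x = features, y = rates,
                                      ntree = num_trees, ...)
  structure(list(model = model, cv_pearson = cv_pearson, cv_mse = cv_mse,
                 oof_predictions = oof, folds = fold, n = n,
                 num_trees = num_trees),
            class = "rate_predictor")
}

#' @export
print.rate_predictor <- function(x, ...) {
  cat("<rate_predictor> random forest, ", x$num_trees, " trees, n = ", x$n,
      "; CV Pearson r = ", round(x$cv_pearson, 3),
      ", CV MSE = ", signif(x$cv_mse, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname train_rate_predictor
#' @param x A `rate_predictor`.
#' @param ... Unused.
#' @export
glance.rate_predictor <- function(x, ...) {
  tibble(n = x$n, num_trees = x$num_trees,
         cv_pearson = x$cv_pearson, cv_mse = x$cv_mse)
}

#' Predict rates for new intervals
#'
#' @param object A `rate_predictor`.
#' @param features New feature tibble (same columns as training).
#' @param ... Unused.
#' @return Numeric vector of predicted rates.
#' @export
predict.rate_predictor <- function(object, features, ...) {
  features <- as.data.frame(features)
  features$meth_missing <- NULL
  lv <- object$model$forest$xlevels[["chrom"]]
  if ("chrom" %in% names(features) && is.character(lv)) {
    features$chrom <- factor(as.character(features$chrom), levels = lv)
    if (anyNA(features$chrom)) {
      abort("prediction features contain chromosomes unseen in training")
    }
  }
  as.numeric(predict(object$model, features))
}

#' Fraction of the observed valley depth recaptured by a predictor
#'
#' Compares the model-predicted rate difference (mean control minus mean
#' link) with the observed difference:
#' `(mean pred control - mean pred link) / (mean obs control - mean obs link)`.
#' A perfect rate oracle gives 1, a constant predictor 0.
#'
#' @param predictor A `rate_predictor`.
#' @param link_features,control_features Feature tibbles for link spans and
#'   their matched controls.
#' @param link_rates,control_rates Observed rates for the same rows.
#' @return List: `fraction` (raw), `fraction_clipped` (into \[0, 1\]),
#'   `observed_difference`, `predicted_difference`, `undefined` (TRUE when
#'   the observed difference is 0).
#' @export
depletion_recapitulation <- function(predictor, link_features, control_features,
                                     link_rates, control_rates) {
  obs_diff <- mean(control_rates) - mean(link_rates)
  pred_diff <- mean(predict(predictor, control_features)) -
    mean(predict(predictor, link_features))
  if (obs_diff == 0) {
    return(list(fraction = NA_real_, fraction_clipped = NA_real_,
                observed_difference = 0, predicted_difference = pred_diff,
                undefined = TRUE))
  }
  frac <- pred_diff / obs_diff
  list(fraction = frac, fraction_clipped = min(1, max(0, frac)),
       observed_difference = obs_diff, predicted_difference = pred_diff,
       undefined = FALSE)
}
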