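#' Plot mean recombination rate against link distance
#'
#' Observed (coloured) and control (black) mean-rate curves per distance
#' class, with ribbons at mean +/- sd x 1.96 / 10.
#'
#' @param object A [mean_rate_by_distance()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_by_distance <- function(object, ...) {
  d <- dplyr::filter(object, .data$n > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_rate - .data$ci_half,
                                      ymax = .data$mean_rate + .data$ci_half),
                         fill = "orange", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_rate), colour = "orange")
  if ("mean_control" %in% names(d)) {
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_control - .data$ci_half_control,
                                        ymax = .data$mean_control + .data$ci_half_control),
                           fill = "grey40", alpha = 0.3) +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean_control), colour = "black")
  }
  p +
    ggplot2::facet_wrap(~distance_class, scales = "free_x") +
    ggplot2::labs(x = "anchor distance (bp)", y = "mean rate (cM/Mb)",
                  title = "Recombination rate by link distance",
                  subtitle = "ribbon: mean \u00b1 sd \u00d7 1.96/10; black: matched controls") +
    ggplot2::theme_minimal()
}

#' Plot a valley test result
#'
#' Observed versus control mean and median rates per distance class, with
#' significance stars at the configured threshold.
#'
#' @param object A `valley_test` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.valley_test <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("mean_observed", "mean_control"),
                        names_to = "group", values_to = "rate") |>
    dplyr::mutate(group = ifelse(.data$group == "mean_observed",
                                 "links", "matched controls"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance_class, y = .data$rate,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = dplyr::filter(tidy(object), .data$significant),
      ggplot2::aes(x = .data$distance_class,
                   y = pmax(.data$mean_observed, .data$mean_control) * 1.05,
                   label = "*"),
      inherit.aes = FALSE, size = 6) +
    ggplot2::scale_fill_manual(values = c("links" = "orange",
                                          "matched controls" = "grey40")) +
    ggplot2::labs(x = "distance class", y = "mean rate (cM/Mb)",
                  fill = NULL, title = "Recombination rate valley test") +
    ggplot2::theme_minimal()
}

#' Plot rate by methylation quantile
#'
#' @param object A [quantile_rate_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.quantile_rate_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$quantile, y = .data$mean_rate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rate - .data$sd_rate,
                                        ymax = .data$mean_rate + .data$sd_rate),
                           width = 0.2) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "methylation quantile", y = "mean rate (cM/Mb)",
                  title = "Recombination rate by methylation quantile",
                  subtitle = "error bars: standard deviation") +
    ggplot2::theme_minimal()
}
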