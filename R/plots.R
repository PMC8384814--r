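# approximate 2D head layout for the 19-channel 10-20 montage
layout_10_20 <- function() {
  tibble::tibble(
    channel = montage_10_20(),
    x = c(-0.3, 0.3, -0.4, 0.4, -0.5, 0.5, -0.4, 0.4, -0.3, 0.3,
          -0.7, 0.7, -0.85, 0.85, -0.7, 0.7, 0, 0, 0),
    y = c(0.85, 0.85, 0.45, 0.45, 0, 0, -0.45, -0.45, -0.85, -0.85,
          0.55, 0.55, 0, 0, -0.55, -0.55, 0.45, 0, -0.45)
  )
}

#' Plot microstate template topographies
#'
#' One panel per template. Channels with known 10-20 positions are placed
#' on a schematic head; other montages fall back to a channel-index strip.
#'
#' @param object a [template_set()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.template_set <- function(object, ...) {
  df <- tidy(object)
  lay <- layout_10_20()
  if (all(df$channel %in% lay$channel)) {
    df <- dplyr::left_join(df, lay, by = "channel")
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                     colour = .data$potential)) +
      ggplot2::geom_point(size = 5) +
      ggplot2::scale_colour_gradient2(low = "blue", mid = "white", high = "red") +
      ggplot2::facet_wrap(~template) +
      ggplot2::coord_equal() +
      ggplot2::theme_void() +
      ggplot2::labs(colour = "a.u.")
  } else {
    df$channel <- factor(df$channel, levels = object$channels)
    ggplot2::ggplot(df, ggplot2::aes(.data$channel, .data$potential)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~template) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
  }
}

#' Plot a Krzanowski-Lai selection curve
#'
#' Dispersion and KL index against the candidate number of templates, with
#' the chosen k marked.
#'
#' @param object a `kl_curve` from [kl_select()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.kl_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  chosen <- attr(object, "chosen_k")
  ggplot2::ggplot(df[!is.na(df$kl), ], ggplot2::aes(.data$k, .data$kl)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = chosen, linetype = "dashed") +
    ggplot2::labs(x = "number of templates k", y = "KL index") +
    ggplot2::theme_minimal()
}

#' Plot a log-log scaling fit
#'
#' @param object a `scaling_fit` from [loglog_fit()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.scaling_fit <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$log_freq, .data$log_metric)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = attr(object, "slope"),
                         intercept = attr(object, "intercept"),
                         linetype = "dashed") +
    ggplot2::labs(x = "ln median band frequency (Hz)",
                  y = paste0("ln ", attr(object, "metric")),
                  title = sprintf("slope %.3f, R² %.3f",
                                  attr(object, "slope"),
                                  attr(object, "r_squared"))) +
    ggplot2::theme_minimal()
}

#' Plot microstate metrics by state
#'
#' Mean with one standard error per template and sleep state, one panel per
#' metric — the standard summary figure for a two-state microstate study.
#'
#' @param metrics metrics tibble as produced by [backfit_epoch()] /
#'   [run_study()] (needs `template`, `state` and metric columns).
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(metrics,
                              cols = dplyr::any_of(c("duration_ms",
                                                     "occurrence_hz",
                                                     "coverage_pct")),
                              names_to = "metric", values_to = "value")
  summ <- long |>
    dplyr::group_by(.data$metric, .data$template, .data$state) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     se = stats::sd(.data$value, na.rm = TRUE) /
                       sqrt(sum(!is.na(.data$value))),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$template, .data$mean,
                                     fill = .data$state)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "microstate template", y = NULL)
}

#' Plot a permutation/randomization null distribution
#'
#' Histogram of the null statistics with the observed value marked; works
#' for both the syntax randomization test and TANOVA.
#'
#' @param object a `syntax_test` or `tanova_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.syntax_test <- function(object, ...) {
  plot_null_dist(object$null_distances, object$distance,
                 "chi-square distance D")
}

#' @rdname autoplot.syntax_test
#' @export
autoplot.tanova_result <- function(object, ...) {
  plot_null_dist(object$null_effects, object$effect,
                 "global dissimilarity effect")
}

plot_null_dist <- function(null_values, observed, xlab) {
  df <- tibble::tibble(value = null_values)
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = observed, colour = "red") +
    ggplot2::labs(x = xlab, y = "count") +
    ggplot2::theme_minimal()
}
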