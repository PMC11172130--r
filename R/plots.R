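#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a window-length performance sweep
#'
#' Metric means with a +/- one-standard-deviation ribbon across window
#' lengths, one panel per metric.
#'
#' @param object A `sweep_result` from [time_window_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(
      dplyr::all_of(c("accuracy", "f1_macro", "gmean_macro", "kappa")),
      names_to = "metric", values_to = "mean"
    ) |>
    dplyr::mutate(sd = dplyr::case_when(
      .data$metric == "accuracy" ~ .data$accuracy_sd,
      .data$metric == "f1_macro" ~ .data$f1_macro_sd,
      .data$metric == "gmean_macro" ~ .data$gmean_macro_sd,
      .data$metric == "kappa" ~ .data$kappa_sd
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "time window (s)", y = "cross-validated metric")
}

#' Plot an RFE iteration trace
#'
#' Metric trajectories against remaining subset size, with the optimal
#' subset marked.
#'
#' @param object An `rfe_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rfe_trace
#' @export
autoplot.rfe_trace <- function(object, ...) {
  long <- object$trace |>
    tidyr::pivot_longer(
      dplyr::all_of(c("accuracy", "f1_macro", "gmean_macro", "kappa")),
      names_to = "metric", values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_features, y = .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = length(object$best_features),
                        linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "remaining features", y = "cross-validated metric")
}

#' Plot rhythm / region attribution of a selected subset
#'
#' @param subset Feature names or indices (e.g. `rfe$best_features`).
#' @return A ggplot with endpoint counts per region, split by band.
#' @export
plot_attribution <- function(subset) {
  tab <- region_rhythm_table(subset)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$region, y = .data$n,
                                    fill = .data$band)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "brain region", y = "endpoint count", fill = "rhythm")
}
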