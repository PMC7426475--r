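#' Plot the site-level aggregate table
#'
#' Dot-and-error plot of the per-site mean (+/- SD across thresholds) of one
#' metric for each pipeline, with the overall rows drawn as horizontal
#' reference lines.
#'
#' @param object A `netsign_aggregate` from [aggregate_results()].
#' @param metric One of `"accuracy"`, `"sensitivity"`, `"specificity"`,
#'   `"auc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netsign_aggregate <- function(object, metric = "accuracy", ...) {
  d <- dplyr::filter(
    object, .data$metric == !!metric,
    !.data$site %in% c("Mean", "Weighted Mean")
  )
  ref <- dplyr::filter(
    object, .data$metric == !!metric, .data$site == "Weighted Mean"
  )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$site, y = .data$mean, colour = .data$pipeline
  )) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.5), fatten = 2
    ) +
    ggplot2::geom_hline(
      data = ref,
      ggplot2::aes(yintercept = .data$mean, colour = .data$pipeline),
      linetype = "dashed", alpha = 0.6
    ) +
    ggplot2::labs(
      x = NULL, y = metric,
      title = sprintf("Per-site %s by sign-handling pipeline", metric),
      subtitle = "error bars: SD across thresholds; dashed: weighted mean"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Threshold-wise p-value heatmap for one pipeline pair
#'
#' Site-by-threshold heatmap of the Welch p-values at matched thresholds,
#' with significant cells (adjusted p < alpha) outlined.
#'
#' @param comparisons A `netsign_comparisons` from
#'   [pipeline_comparison_suite()].
#' @param metric Metric to display.
#' @param pair Character vector of the two pipelines (order as stored).
#' @param alpha Significance level for highlighting (default 0.05).
#' @return A ggplot object.
#' @export
plot_threshold_heatmap <- function(comparisons, metric = "accuracy",
                                   pair = c("abs", "neg"), alpha = 0.05) {
  d <- comparisons$welch_thresholdwise |>
    dplyr::filter(
      .data$metric == !!metric,
      .data$pipeline_a == pair[1], .data$pipeline_b == pair[2]
    )
  if (nrow(d) == 0) stop("no comparisons for that metric/pair")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$site, y = factor(.data$threshold), fill = .data$p_value
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = dplyr::filter(d, !is.na(.data$adjusted_p),
                           .data$adjusted_p < alpha),
      fill = NA, colour = "yellow", linewidth = 1
    ) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "proportional threshold", fill = "p",
      title = sprintf("%s vs %s: %s (Welch p, matched thresholds)",
                      pair[1], pair[2], metric)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the AUC-age regression
#'
#' Scatter of per-site AUC means against site age means with the fitted
#' polynomial curve.
#'
#' @param object A `netsign_agefit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netsign_agefit <- function(object, ...) {
  grid <- tibble::tibble(
    age = seq(min(object$data$age), max(object$data$age), length.out = 200)
  )
  grid$auc <- stats::predict(object$fit, newdata = grid)
  g <- generics::glance(object)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$age, .data$auc)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(
      x = "site mean age (years)", y = "site mean AUC",
      title = sprintf("AUC vs age, degree-%d fit", object$degree),
      subtitle = sprintf("R² = %.3f, F-test p = %.3g",
                         g$r_squared, g$f_p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
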