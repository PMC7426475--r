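#' Welch's unequal-variance t-test
#'
#' Two-tailed Welch test with Welch-Satterthwaite degrees of freedom, via
#' [stats::t.test()]. Two constant, equal samples return the sentinel
#' `t = 0, p = 1`; two constant, different samples return `p = 0` with a
#' warning (an infinite t in the limit).
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @return One-row tibble: `t_statistic`, `dof`, `p_value`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(
        t_statistic = 0, dof = length(a) + length(b) - 2, p_value = 1
      ))
    }
    warning("both samples constant but different; p-value sentinel 0")
    return(tibble::tibble(
      t_statistic = sign(mean(a) - mean(b)) * Inf,
      dof = length(a) + length(b) - 2, p_value = 0
    ))
  }
  ht <- tryCatch(
    stats::t.test(a, b, var.equal = FALSE),
    error = function(e) NULL # t.test refuses near-constant data
  )
  if (!is.null(ht)) {
    return(tibble::tibble(
      t_statistic = unname(ht$statistic), dof = unname(ht$parameter),
      p_value = ht$p.value
    ))
  }
  # closed-form Welch fallback (one sample constant, the other not)
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  tibble::tibble(
    t_statistic = t_stat, dof = dof,
    p_value = 2 * stats::pt(-abs(t_stat), dof)
  )
}

# paired t-test with the constant-difference sentinel
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(
        t_statistic = 0, dof = length(d) - 1, p_value = 1
      ))
    }
    warning("constant nonzero paired differences; p-value sentinel 0")
    return(tibble::tibble(
      t_statistic = sign(mean(d)) * Inf, dof = length(d) - 1, p_value = 0
    ))
  }
  ht <- tryCatch(
    stats::t.test(a, b, paired = TRUE),
    error = function(e) NULL # t.test refuses near-constant differences
  )
  if (is.null(ht)) {
    t_stat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    return(tibble::tibble(
      t_statistic = t_stat, dof = length(d) - 1,
      p_value = 2 * stats::pt(-abs(t_stat), length(d) - 1)
    ))
  }
  tibble::tibble(
    t_statistic = unname(ht$statistic), dof = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Holm-Sidak step-down multiple-comparison correction
#'
#' Sorts the p-values ascending, applies the Sidak adjustment
#' `1 - (1 - p_(i))^(m - i + 1)` at each rank, enforces step-down
#' monotonicity with a running maximum, and returns the adjusted values in
#' the original order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order; elementwise no smaller
#'   than the input.
#' @examples
#' holm_sidak(c(0.01, 0.04)) # 0.0199, 0.04
#' @export
holm_sidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# per-repetition threshold-averaged metrics: the "trial level" unit
trial_level <- function(results) {
  results |>
    tidyr::pivot_longer(
      c("accuracy", "sensitivity", "specificity", "auc"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$pipeline, .data$site, .data$metric,
                    .data$repetition) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
}

#' Statistical comparison of sign-handling pipelines
#'
#' Three comparison families, each Holm-Sidak corrected per metric within
#' its family:
#' * `welch_site`: per-site Welch tests on the trial-level (threshold-
#'   averaged) repetition metrics, one test per pipeline pair, metric and
#'   site.
#' * `welch_thresholdwise`: Welch tests at matched thresholds (repetitions as
#'   units), one test per pipeline pair, metric, site and threshold — the
#'   heatmap analogue.
#' * `paired_t`: paired t-tests across sites on the site-mean metrics, one
#'   test per pipeline pair and metric.
#'
#' @param results A `netsign_results` tibble covering >= 2 pipelines on a
#'   common (site, threshold, repetition) grid.
#' @return A `netsign_comparisons` list of the three tibbles, each with
#'   `p_value` and `adjusted_p`.
#' @export
pipeline_comparison_suite <- function(results) {
  pls <- sort(unique(results$pipeline))
  if (length(pls) < 2) stop("need results for at least 2 pipelines")
  check <- results |>
    dplyr::count(.data$site, .data$threshold, .data$repetition) |>
    dplyr::filter(.data$n != length(pls))
  if (nrow(check) > 0) {
    stop(
      "pipelines do not share a common grid; first missing cells:\n",
      paste(utils::capture.output(print(utils::head(check))), collapse = "\n")
    )
  }
  pairs <- utils::combn(pls, 2, simplify = FALSE)

  tl <- trial_level(results)
  welch_site <- purrr::map_dfr(pairs, function(pr) {
    tl |>
      dplyr::filter(.data$pipeline %in% pr) |>
      dplyr::group_by(.data$site, .data$metric) |>
      dplyr::group_modify(function(d, key) {
        welch_test(
          d$value[d$pipeline == pr[1]], d$value[d$pipeline == pr[2]]
        )
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(pipeline_a = pr[1], pipeline_b = pr[2])
  }) |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(adjusted_p = holm_sidak(.data$p_value)) |>
    dplyr::ungroup()

  long <- results |>
    tidyr::pivot_longer(
      c("accuracy", "sensitivity", "specificity", "auc"),
      names_to = "metric", values_to = "value"
    )
  welch_thr <- purrr::map_dfr(pairs, function(pr) {
    long |>
      dplyr::filter(.data$pipeline %in% pr, !is.na(.data$value)) |>
      dplyr::group_by(.data$site, .data$threshold, .data$metric) |>
      dplyr::group_modify(function(d, key) {
        a <- d$value[d$pipeline == pr[1]]
        b <- d$value[d$pipeline == pr[2]]
        if (length(a) < 2 || length(b) < 2) {
          return(tibble::tibble(
            t_statistic = NA_real_, dof = NA_real_, p_value = NA_real_
          ))
        }
        welch_test(a, b)
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(pipeline_a = pr[1], pipeline_b = pr[2])
  }) |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(
      adjusted_p = replace(
        rep(NA_real_, dplyr::n()), !is.na(.data$p_value),
        holm_sidak(.data$p_value[!is.na(.data$p_value)])
      )
    ) |>
    dplyr::ungroup()

  site_means <- tl |>
    dplyr::group_by(.data$pipeline, .data$site, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  paired <- purrr::map_dfr(pairs, function(pr) {
    site_means |>
      dplyr::filter(.data$pipeline %in% pr) |>
      tidyr::pivot_wider(names_from = "pipeline", values_from = "value") |>
      dplyr::group_by(.data$metric) |>
      dplyr::group_modify(function(d, key) {
        paired_t(d[[pr[1]]], d[[pr[2]]])
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(pipeline_a = pr[1], pipeline_b = pr[2])
  }) |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(adjusted_p = holm_sidak(.data$p_value)) |>
    dplyr::ungroup()

  structure(
    list(
      welch_site = welch_site, welch_thresholdwise = welch_thr,
      paired_t = paired
    ),
    class = "netsign_comparisons"
  )
}

#' Quadratic regression of site AUC on site age mean
#'
#' Ordinary least squares of the per-site mean AUC on a polynomial in the
#' site's mean age (default degree 2, the inverted-U model; degree 3 is
#' available for the steeper tail behaviour sometimes seen).
#'
#' @param site_auc_means,site_age_means Aligned numeric vectors, one value
#'   per site.
#' @param degree Polynomial degree (default 2).
#' @return A `netsign_agefit` wrapping the [stats::lm()] fit; `tidy()` gives
#'   the coefficients, `glance()` the R-squared and overall F-test p-value.
#' @export
auc_age_regression <- function(site_auc_means, site_age_means, degree = 2L) {
  stopifnot(length(site_auc_means) == length(site_age_means))
  if (length(site_auc_means) < degree + 2) {
    stop("need at least degree + 2 sites")
  }
  if (length(unique(site_age_means)) < degree + 1) {
    stop("age means are collinear: fewer than degree + 1 distinct values")
  }
  d <- tibble::tibble(auc = site_auc_means, age = site_age_means)
  fit <- stats::lm(auc ~ poly(age, degree, raw = TRUE), data = d)
  structure(
    list(fit = fit, degree = as.integer(degree), data = d),
    class = "netsign_agefit"
  )
}

#' @export
print.netsign_agefit <- function(x, ...) {
  g <- generics::glance(x)
  cat(sprintf(
    "<netsign_agefit> degree %d: R^2 = %.3f, F-test p = %.4g (n = %d sites)\n",
    x$degree, g$r_squared, g$f_p_value, nrow(x$data)
  ))
  invisible(x)
}
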