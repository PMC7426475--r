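# Per-site, per-group, per-sex demographic summaries of the 17-site ABIDE I
# cohort (age mean, age SD, count). SDs reported for single-subject cells are
# unavailable and recorded as 0.
abide_demographics <- function() {
  tribble_cols <- c("site", "group", "sex", "age_mean", "age_sd", "n")
  raw <- list(
    list("CALTECH", "ASD", "F", 24.35, 6.91, 4L),
    list("CALTECH", "ASD", "M", 28.27, 11.08, 15L),
    list("CALTECH", "HC", "F", 22.77, 4.31, 4L),
    list("CALTECH", "HC", "M", 29.51, 11.83, 14L),
    list("CMU", "ASD", "F", 27.00, 6.93, 3L),
    list("CMU", "ASD", "M", 26.18, 5.88, 11L),
    list("CMU", "HC", "F", 26.00, 5.29, 3L),
    list("CMU", "HC", "M", 27.10, 6.12, 10L),
    list("KKI", "ASD", "F", 9.61, 1.85, 4L),
    list("KKI", "ASD", "M", 10.12, 1.38, 16L),
    list("KKI", "HC", "F", 9.49, 0.81, 8L),
    list("KKI", "HC", "M", 10.22, 1.23, 20L),
    list("LEUVEN", "ASD", "F", 14.00, 1.41, 3L),
    list("LEUVEN", "ASD", "M", 18.18, 5.09, 26L),
    list("LEUVEN", "HC", "F", 13.56, 0.75, 5L),
    list("LEUVEN", "HC", "M", 19.01, 5.05, 29L),
    list("MAX_MUN", "ASD", "F", 35.33, 8.50, 3L),
    list("MAX_MUN", "ASD", "M", 24.76, 15.27, 21L),
    list("MAX_MUN", "HC", "F", 32.00, 0.00, 1L),
    list("MAX_MUN", "HC", "M", 24.37, 8.81, 27L),
    list("NYU", "ASD", "F", 18.62, 9.14, 10L),
    list("NYU", "ASD", "M", 14.14, 6.59, 65L),
    list("NYU", "HC", "F", 15.37, 6.45, 26L),
    list("NYU", "HC", "M", 15.76, 6.10, 74L),
    list("OHSU", "ASD", "M", 11.43, 2.18, 12L),
    list("OHSU", "HC", "M", 10.09, 1.12, 14L),
    list("OLIN", "ASD", "F", 19.00, 5.00, 3L),
    list("OLIN", "ASD", "M", 16.06, 3.04, 16L),
    list("OLIN", "HC", "F", 17.50, 3.54, 2L),
    list("OLIN", "HC", "M", 16.54, 3.78, 13L),
    list("PITT", "ASD", "F", 12.60, 0.95, 4L),
    list("PITT", "ASD", "M", 20.03, 7.38, 25L),
    list("PITT", "HC", "F", 16.07, 3.60, 4L),
    list("PITT", "HC", "M", 19.36, 6.97, 23L),
    list("SBL", "ASD", "M", 35.00, 10.43, 15L),
    list("SBL", "HC", "M", 33.73, 6.61, 15L),
    list("SDSU", "ASD", "F", 12.44, 0.00, 1L),
    list("SDSU", "ASD", "M", 14.89, 1.70, 13L),
    list("SDSU", "HC", "F", 13.26, 2.69, 6L),
    list("SDSU", "HC", "M", 14.58, 1.46, 16L),
    list("STANFORD", "ASD", "F", 10.02, 1.63, 4L),
    list("STANFORD", "ASD", "M", 9.99, 1.68, 15L),
    list("STANFORD", "HC", "F", 9.01, 1.01, 4L),
    list("STANFORD", "HC", "M", 10.19, 1.66, 16L),
    list("TRINITY", "ASD", "M", 16.81, 3.17, 22L),
    list("TRINITY", "HC", "M", 17.08, 3.77, 25L),
    list("UCLA", "ASD", "F", 12.46, 3.42, 6L),
    list("UCLA", "ASD", "M", 13.08, 2.34, 48L),
    list("UCLA", "HC", "F", 12.82, 0.89, 6L),
    list("UCLA", "HC", "M", 13.03, 2.04, 38L),
    list("UM", "ASD", "F", 13.53, 3.12, 9L),
    list("UM", "ASD", "M", 13.11, 2.30, 57L),
    list("UM", "HC", "F", 14.78, 2.82, 18L),
    list("UM", "HC", "M", 14.82, 3.85, 56L),
    list("USM", "ASD", "M", 23.46, 8.33, 46L),
    list("USM", "HC", "M", 21.29, 8.35, 25L),
    list("YALE", "ASD", "F", 12.88, 3.00, 8L),
    list("YALE", "ASD", "M", 12.70, 3.14, 20L),
    list("YALE", "HC", "F", 13.52, 2.64, 8L),
    list("YALE", "HC", "M", 12.34, 2.79, 20L)
  )
  df <- purrr::map_dfr(raw, ~ tibble::as_tibble(stats::setNames(.x, tribble_cols)))
  df
}

# collapse per-sex rows of one (site, group) to mixture mean / SD
collapse_group <- function(rows) {
  n <- sum(rows$n)
  mu <- sum(rows$n * rows$age_mean) / n
  # mixture variance: within-sex variance plus between-sex spread
  v <- sum(rows$n * (rows$age_sd^2 + rows$age_mean^2)) / n - mu^2
  tibble::tibble(
    n = n, age_mean = mu, age_sd = sqrt(max(v, 0)),
    f_female = sum(rows$n[rows$sex == "F"]) / n
  )
}

#' Default multi-site cohort templates
#'
#' One row per imaging site of the 17-site reference cohort, with per-group
#' sample sizes, age distributions and female fractions collapsed across sex,
#' plus generator knobs (`noise_scale`, `n_timepoints`) that model residual
#' site differences in signal amplitude and run length.
#'
#' @param n_timepoints Time points per subject (default 150, a typical
#'   resting-state run length).
#' @param noise_scale Per-site signal-amplitude multiplier (default 1 for all
#'   sites).
#' @return A tibble with one row per site and columns `site`, `n_asd`, `n_hc`,
#'   `age_mean_asd`, `age_sd_asd`, `age_mean_hc`, `age_sd_hc`,
#'   `f_female_asd`, `f_female_hc`, `noise_scale`, `n_timepoints`.
#' @examples
#' default_site_templates()
#' @export
default_site_templates <- function(n_timepoints = 150L, noise_scale = 1) {
  demo <- abide_demographics()
  out <- demo |>
    dplyr::group_by(.data$site, .data$group) |>
    dplyr::group_modify(~ collapse_group(.x)) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(
      names_from = "group",
      values_from = c("n", "age_mean", "age_sd", "f_female"),
      names_glue = "{.value}_{tolower(group)}"
    ) |>
    dplyr::arrange(.data$site)
  out$noise_scale <- noise_scale
  out$n_timepoints <- as.integer(n_timepoints)
  dplyr::rename(out, n_asd = "n_asd", n_hc = "n_hc")
}

#' A minimal site-template table for small experiments
#'
#' Balanced sites with equal group sizes; useful for desk-scale simulation
#' studies where the full 17-site cohort would be overkill.
#'
#' @param n_sites Number of sites.
#' @param n_per_group Subjects per diagnostic group per site.
#' @param age_means Recycled vector of per-site age means (applied to both
#'   groups).
#' @param age_sd Age SD (all sites/groups).
#' @inheritParams default_site_templates
#' @return A site-template tibble (same columns as
#'   [default_site_templates()]).
#' @export
toy_site_templates <- function(n_sites = 4, n_per_group = 20,
                               age_means = c(10, 15, 20, 25), age_sd = 3,
                               n_timepoints = 150L, noise_scale = 1) {
  am <- rep_len(age_means, n_sites)
  tibble::tibble(
    site = sprintf("SITE%02d", seq_len(n_sites)),
    n_asd = as.integer(n_per_group), n_hc = as.integer(n_per_group),
    age_mean_asd = am, age_sd_asd = age_sd,
    age_mean_hc = am, age_sd_hc = age_sd,
    f_female_asd = 0.2, f_female_hc = 0.2,
    noise_scale = noise_scale, n_timepoints = as.integer(n_timepoints)
  )
}
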