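#' Specification of a synthetic connectivity cohort
#'
#' Describes the population the generator draws from: regions are partitioned
#' into modules (round-robin by index, so unequal sizes are deterministic);
#' the time series of one subject is a zero-mean multivariate normal whose
#' correlation is `within_module_corr` inside a module and a group-dependent
#' `between_module_corr_*` across modules. A group difference in the
#' between-module correlation plants a topological ASD/HC difference at the
#' network level. If `apply_gsr` is set, the generated series are
#' global-signal-regressed, which forces anti-correlations.
#'
#' @param n_regions Number of ROIs (N).
#' @param n_modules Number of covariance modules (M).
#' @param within_module_corr Correlation between regions of the same module,
#'   in (0, 1).
#' @param between_module_corr_hc,between_module_corr_asd Correlation between
#'   regions of different modules for each diagnostic group, in (-1, 1).
#' @param apply_gsr Remove the global signal from each generated subject?
#' @param gsr_method `"mean_subtract"` removes the cross-ROI mean at every
#'   time point; `"regress"` regresses each ROI series on the global mean
#'   series and keeps the residual.
#' @param age_min Lower clip for sampled ages, years.
#' @return A `netsign_cohort_spec` list; construction fails if either group's
#'   implied covariance is not positive semi-definite.
#' @examples
#' spec <- cohort_spec(n_regions = 20, n_modules = 4)
#' @export
cohort_spec <- function(n_regions = 200L, n_modules = 4L,
                        within_module_corr = 0.5,
                        between_module_corr_hc = 0.1,
                        between_module_corr_asd = 0.3,
                        apply_gsr = TRUE,
                        gsr_method = c("mean_subtract", "regress"),
                        age_min = 6) {
  gsr_method <- match.arg(gsr_method)
  stopifnot(
    n_regions >= 2, n_modules >= 1,
    within_module_corr > 0, within_module_corr < 1,
    abs(between_module_corr_hc) < 1, abs(between_module_corr_asd) < 1
  )
  spec <- structure(
    list(
      n_regions = as.integer(n_regions), n_modules = as.integer(n_modules),
      within_module_corr = within_module_corr,
      between_module_corr_hc = between_module_corr_hc,
      between_module_corr_asd = between_module_corr_asd,
      apply_gsr = isTRUE(apply_gsr), gsr_method = gsr_method,
      age_min = age_min
    ),
    class = "netsign_cohort_spec"
  )
  # fail fast on invalid covariance requests
  group_covariance(spec, "HC")
  group_covariance(spec, "ASD")
  spec
}

# module id per region, round-robin by index
module_assignment <- function(spec) {
  ((seq_len(spec$n_regions) - 1L) %% spec$n_modules) + 1L
}

# population covariance (unit variances) for one diagnostic group;
# PSD verified by eigenvalue check, tiny negatives clipped, gross ones rejected
group_covariance <- function(spec, group) {
  between <- if (group == "ASD") spec$between_module_corr_asd else
    spec$between_module_corr_hc
  mod <- module_assignment(spec)
  same <- outer(mod, mod, "==")
  S <- ifelse(same, spec$within_module_corr, between)
  diag(S) <- 1
  ev <- eigen(S, symmetric = TRUE)
  lam <- ev$values
  if (min(lam) < -1e-6) {
    stop(sprintf(
      paste0(
        "requested covariance for group %s is not positive semi-definite ",
        "(min eigenvalue %.3g): within_module_corr = %g, ",
        "between_module_corr = %g"
      ),
      group, min(lam), spec$within_module_corr, between
    ))
  }
  if (min(lam) < -1e-10) {
    S <- ev$vectors %*% (pmax(lam, 0) * t(ev$vectors))
    S <- (S + t(S)) / 2
  }
  S
}

# remove the global (cross-ROI mean) signal from an N x T matrix
remove_global_signal <- function(X, method = "mean_subtract") {
  gs <- colMeans(X)
  if (method == "mean_subtract") {
    sweep(X, 2, gs)
  } else {
    t(apply(X, 1, function(row) stats::lsfit(gs, row)$residuals))
  }
}

#' Generate one subject's ROI time series
#'
#' Draws an N x T matrix from the group's block-covariance multivariate
#' normal, scales by the site's `noise_scale`, and (if the spec asks for it)
#' removes the global signal.
#'
#' @param spec A [cohort_spec()].
#' @param group `"ASD"` or `"HC"`.
#' @param n_timepoints Number of time points T.
#' @param noise_scale Positive amplitude multiplier.
#' @return N x T numeric matrix with ROI labels as row names. Uses the
#'   current RNG state; seed externally for reproducibility.
#' @export
generate_subject <- function(spec, group = c("HC", "ASD"),
                             n_timepoints = 150L, noise_scale = 1) {
  group <- match.arg(group)
  stopifnot(n_timepoints >= 2, noise_scale > 0)
  S <- group_covariance(spec, group)
  X <- t(MASS::mvrnorm(n_timepoints, mu = rep(0, spec$n_regions), Sigma = S))
  X <- X * noise_scale
  if (spec$apply_gsr) X <- remove_global_signal(X, spec$gsr_method)
  rownames(X) <- sprintf("ROI%03d", seq_len(spec$n_regions))
  X
}

#' Generate a full multi-site cohort
#'
#' Subjects are generated site by site (sites in the order given), ASD group
#' first, with ages drawn from the per-site normal clipped at
#' `spec$age_min` and sex sampled from the per-site female fraction.
#'
#' @param spec A [cohort_spec()].
#' @param sites Site-template tibble ([default_site_templates()] or
#'   [toy_site_templates()]).
#' @param seed Integer; the whole cohort is deterministic given this seed.
#' @return A `netsign_cohort`: list with `ts` (named list of N x T matrices)
#'   and `phenotype` (tibble: `subject_id`, `site`, `diagnosis`, `sex`,
#'   `age`).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_regions = 10, n_modules = 2),
#'                           toy_site_templates(2, 3), seed = 1)
#' @export
generate_cohort <- function(spec, sites, seed = 1L) {
  stopifnot(inherits(spec, "netsign_cohort_spec"), nrow(sites) >= 1)
  if (anyDuplicated(sites$site)) {
    stop("duplicate site names: ",
         paste(unique(sites$site[duplicated(sites$site)]), collapse = ", "))
  }
  withr::local_seed(seed)
  ts <- list()
  rows <- list()
  counter <- 0L
  for (s in seq_len(nrow(sites))) {
    st <- sites[s, ]
    for (group in c("ASD", "HC")) {
      n_g <- if (group == "ASD") st$n_asd else st$n_hc
      if (n_g == 0) next
      mu <- if (group == "ASD") st$age_mean_asd else st$age_mean_hc
      sdv <- if (group == "ASD") st$age_sd_asd else st$age_sd_hc
      ff <- if (group == "ASD") st$f_female_asd else st$f_female_hc
      for (i in seq_len(n_g)) {
        counter <- counter + 1L
        id <- sprintf("%s_%05d", st$site, counter)
        age <- max(spec$age_min, stats::rnorm(1, mu, sdv))
        sex <- if (stats::runif(1) < ff) "F" else "M"
        ts[[id]] <- generate_subject(spec, group,
          n_timepoints = st$n_timepoints, noise_scale = st$noise_scale
        )
        rows[[counter]] <- tibble::tibble(
          subject_id = id, site = st$site, diagnosis = group,
          sex = sex, age = age
        )
      }
    }
  }
  structure(
    list(ts = ts, phenotype = dplyr::bind_rows(rows)),
    class = "netsign_cohort"
  )
}

#' @export
print.netsign_cohort <- function(x, ...) {
  ph <- x$phenotype
  cat(sprintf(
    "<netsign_cohort> %d subjects, %d sites (%d ASD / %d HC)\n",
    nrow(ph), dplyr::n_distinct(ph$site),
    sum(ph$diagnosis == "ASD"), sum(ph$diagnosis == "HC")
  ))
  invisible(x)
}

#' Write / read a cohort as text files
#'
#' One tab-delimited file per subject (rows = time points, columns = ROIs,
#' header row of ROI labels), mirroring the layout of C-PAC ROI extracts,
#' plus `phenotype.csv` with columns `SUB_ID`, `SITE_ID`, `DX_GROUP`,
#' `SEX`, `AGE_AT_SCAN`.
#'
#' @param cohort A `netsign_cohort`.
#' @param dir Output directory (created if missing).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   `netsign_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$ts)) {
    X <- t(cohort$ts[[id]]) # time points x ROIs on disk
    utils::write.table(X, file.path(dir, paste0(id, "_rois.1D")),
      sep = "\t", row.names = FALSE, col.names = rownames(cohort$ts[[id]]),
      quote = FALSE
    )
  }
  ph <- cohort$phenotype
  utils::write.csv(
    data.frame(
      SUB_ID = ph$subject_id, SITE_ID = ph$site, DX_GROUP = ph$diagnosis,
      SEX = ph$sex, AGE_AT_SCAN = ph$age
    ),
    file.path(dir, "phenotype.csv"),
    row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ph_raw <- utils::read.csv(file.path(dir, "phenotype.csv"),
    stringsAsFactors = FALSE
  )
  phenotype <- tibble::tibble(
    subject_id = as.character(ph_raw$SUB_ID), site = ph_raw$SITE_ID,
    diagnosis = ph_raw$DX_GROUP, sex = ph_raw$SEX, age = ph_raw$AGE_AT_SCAN
  )
  ts <- lapply(phenotype$subject_id, function(id) {
    X <- as.matrix(utils::read.delim(file.path(dir, paste0(id, "_rois.1D"))))
    t(X)
  })
  names(ts) <- phenotype$subject_id
  structure(list(ts = ts, phenotype = phenotype), class = "netsign_cohort")
}
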