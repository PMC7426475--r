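#' Leave-one-site-out folds
#'
#' One fold per distinct site, ordered by site label: the fold's test set is
#' exactly that site's subjects, its training set everyone else.
#'
#' @param phenotype Tibble with columns `subject_id` and `site`.
#' @return Tibble with columns `test_site`, `train_subjects`, `test_subjects`
#'   (list-columns of subject ids).
#' @export
loso_split <- function(phenotype) {
  sites <- sort(unique(phenotype$site))
  if (length(sites) < 2) stop("leave-one-site-out needs at least 2 sites")
  tibble::tibble(
    test_site = sites,
    train_subjects = lapply(sites, function(s) {
      phenotype$subject_id[phenotype$site != s]
    }),
    test_subjects = lapply(sites, function(s) {
      phenotype$subject_id[phenotype$site == s]
    })
  )
}

#' Classification metrics under the HC = 1 convention
#'
#' Confusion metrics use the 0.5 probability cut (p >= 0.5 predicts label 1).
#' Sensitivity is the fraction of true label-1 (healthy-control) subjects
#' predicted 1; specificity the fraction of true label-0 (case) subjects
#' predicted 0. AUC is the Mann-Whitney statistic with ties counted half;
#' it is `NA` when only one class is present.
#'
#' @param labels Numeric 0/1 vector.
#' @param probabilities Predicted class-1 probabilities, aligned with
#'   `labels`.
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`, `auc`.
#' @export
compute_metrics <- function(labels, probabilities) {
  stopifnot(length(labels) == length(probabilities))
  pred <- as.numeric(probabilities >= 0.5)
  pos <- labels == 1
  neg <- labels == 0
  auc <- if (any(pos) && any(neg)) {
    r <- rank(probabilities, ties.method = "average")
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(neg))
  } else {
    NA_real_
  }
  tibble::tibble(
    accuracy = mean(pred == labels),
    sensitivity = if (any(pos)) mean(pred[pos] == 1) else NA_real_,
    specificity = if (any(neg)) mean(pred[neg] == 0) else NA_real_,
    auc = auc
  )
}

# labels under the fixed convention: healthy control = 1, case = 0
diagnosis_labels <- function(diagnosis) as.numeric(diagnosis == "HC")

#' Run the full pipeline-comparison experiment
#'
#' For every sign-handling pipeline and proportional threshold, extracts the
#' per-subject graph features (optionally appending per-fold PCA components of
#' the signed connectivity matrix), then runs leave-one-site-out
#' cross-validation with `n_repeats` repetitions per fold. Standardization
#' (and PCA, when requested) is fit on the training fold only; repetition `r`
#' trains with seed `base_seed + r`, so the whole experiment is deterministic
#' given `base_seed`.
#'
#' @param cohort A `netsign_cohort` (or any list with `ts` and `phenotype`
#'   in the same shape).
#' @param pipelines Character subset of `c("pos", "neg", "abs")`.
#' @param thresholds Proportional thresholds, e.g. [threshold_grid()].
#' @param cfg An [mlp_config()]; its `seed` field is overridden per
#'   repetition.
#' @param n_repeats Repetitions per fold (default 5).
#' @param base_seed Base seed for the repetition seeds.
#' @param use_pca Append PCA components of the connectivity matrix?
#' @param pca_k Number of PCA components when `use_pca` is set.
#' @return A `netsign_results` tibble: one row per (site, pipeline,
#'   threshold, repetition) with the four metrics and the test-set size.
#' @export
run_experiment <- function(cohort, pipelines = c("pos", "neg", "abs"),
                           thresholds = threshold_grid(),
                           cfg = mlp_config(), n_repeats = 5,
                           base_seed = 0L, use_pca = FALSE, pca_k = 600L) {
  ph <- cohort$phenotype
  conn <- lapply(cohort$ts, pearson_connectivity)
  folds <- loso_split(ph)
  out <- list()
  for (pl in pipelines) {
    weights <- lapply(conn, apply_pipeline, mode = pl)
    for (ti in seq_along(thresholds)) {
      p <- thresholds[[ti]]
      graphs <- lapply(weights, proportional_threshold, p = p)
      # community seed tied to (subject, threshold) for reproducible features
      feats <- graph_feature_matrix(graphs,
        seeds = seq_along(graphs) * 1000L + ti
      )
      fm <- feats$values[ph$subject_id, , drop = FALSE]
      for (fi in seq_len(nrow(folds))) {
        fold <- folds[fi, ]
        tr <- ph$subject_id %in% fold$train_subjects[[1]]
        te <- !tr
        Xtr <- fm[tr, , drop = FALSE]
        Xte <- fm[te, , drop = FALSE]
        if (use_pca) {
          pca <- suppressWarnings(fit_pca(conn[ph$subject_id[tr]], K = pca_k))
          ptr <- t(vapply(
            conn[ph$subject_id[tr]],
            function(C) transform_pca(pca, C), numeric(pca$K)
          ))
          pte <- t(vapply(
            conn[ph$subject_id[te]],
            function(C) transform_pca(pca, C), numeric(pca$K)
          ))
          Xtr <- cbind(Xtr, ptr)
          Xte <- cbind(Xte, pte)
        }
        std <- suppressWarnings(standardize(Xtr, Xte))
        ytr <- diagnosis_labels(ph$diagnosis[tr])
        yte <- diagnosis_labels(ph$diagnosis[te])
        for (r in seq_len(n_repeats)) {
          rcfg <- cfg
          rcfg$seed <- as.integer(base_seed + r)
          model <- train_mlp(std[[1]], ytr, rcfg)
          met <- compute_metrics(yte, predict_mlp(model, std[[2]]))
          out[[length(out) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(
              site = fold$test_site, pipeline = pl, threshold = p,
              repetition = r, n_test = sum(te)
            ),
            met
          )
        }
      }
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("netsign_results", class(res))
  res
}

#' Aggregate fold results into the site-level summary table
#'
#' Per site and pipeline: each repetition's metrics are first averaged across
#' thresholds (the trial-level average), then the table reports the mean and
#' SD of those per-threshold means across thresholds and repetitions —
#' specifically, the mean and SD across thresholds of the per-threshold
#' repetition means. Two overall rows close the table: `Mean` (unweighted
#' mean of site means) and `Weighted Mean` (weighted by site test-set size).
#' Folds with undefined AUC are dropped from the AUC aggregate, with the
#' dropped count in `n_undefined_auc`.
#'
#' @param results A `netsign_results` tibble from [run_experiment()].
#' @return A `netsign_aggregate` tibble in long metric layout: `pipeline`,
#'   `site`, `metric`, `mean`, `sd`, `n_undefined_auc`.
#' @export
aggregate_results <- function(results) {
  stopifnot(nrow(results) > 0)
  long <- results |>
    tidyr::pivot_longer(
      c("accuracy", "sensitivity", "specificity", "auc"),
      names_to = "metric", values_to = "value"
    )
  # per-threshold repetition mean, then moments across thresholds
  per_site <- long |>
    dplyr::group_by(.data$pipeline, .data$site, .data$metric,
                    .data$threshold) |>
    dplyr::summarise(
      thr_mean = mean(.data$value[!is.na(.data$value)]),
      n_undef = sum(is.na(.data$value)),
      n_test = .data$n_test[1],
      .groups = "drop_last"
    ) |>
    dplyr::summarise(
      mean = mean(.data$thr_mean, na.rm = TRUE),
      sd = stats::sd(.data$thr_mean, na.rm = TRUE),
      n_undefined_auc = sum(.data$n_undef),
      n_test = .data$n_test[1],
      .groups = "drop"
    )
  overall <- per_site |>
    dplyr::group_by(.data$pipeline, .data$metric) |>
    dplyr::summarise(
      Mean = mean(.data$mean),
      `Weighted Mean` = sum(.data$mean * .data$n_test) / sum(.data$n_test),
      n_undefined_auc = sum(.data$n_undefined_auc),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("Mean", "Weighted Mean"),
      names_to = "site", values_to = "mean"
    ) |>
    dplyr::mutate(sd = NA_real_, n_test = NA_integer_)
  out <- dplyr::bind_rows(
    dplyr::select(
      per_site, "pipeline", "site", "metric", "mean", "sd",
      "n_undefined_auc", "n_test"
    ),
    dplyr::select(
      overall, "pipeline", "site", "metric", "mean", "sd",
      "n_undefined_auc", "n_test"
    )
  )
  class(out) <- c("netsign_aggregate", class(out))
  out
}
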