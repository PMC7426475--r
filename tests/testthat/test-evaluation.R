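# small planted-effect cohort shared by the experiment-level tests
tiny_cohort <- function(n_sites = 3, n_per_group = 4, seed = 20,
                        delta = 0.4, n_regions = 8, t_len = 60) {
  spec <- cohort_spec(
    n_regions = n_regions, n_modules = 2, within_module_corr = 0.5,
    between_module_corr_hc = 0, between_module_corr_asd = delta,
    apply_gsr = TRUE
  )
  generate_cohort(
    spec, toy_site_templates(n_sites, n_per_group, n_timepoints = t_len),
    seed = seed
  )
}

test_that("LOSO folds partition the cohort site by site", {
  ph <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:9),
    site = rep(c("B", "A", "C"), each = 3)
  )
  folds <- loso_split(ph)
  expect_equal(folds$test_site, c("A", "B", "C"))
  for (i in 1:3) {
    expect_length(intersect(
      folds$train_subjects[[i]], folds$test_subjects[[i]]
    ), 0)
    expect_setequal(
      c(folds$train_subjects[[i]], folds$test_subjects[[i]]),
      ph$subject_id
    )
    expect_setequal(
      folds$test_subjects[[i]],
      ph$subject_id[ph$site == folds$test_site[i]]
    )
  }
  # union of test sets covers the cohort exactly once
  expect_setequal(unlist(folds$test_subjects), ph$subject_id)
  expect_equal(length(unlist(folds$test_subjects)), nrow(ph))
  expect_error(loso_split(ph[ph$site == "A", ]), "2 sites")
})

test_that("the 17 default site templates give 17 folds", {
  co <- generate_cohort(
    cohort_spec(n_regions = 2, n_modules = 1, within_module_corr = 0.5),
    default_site_templates(n_timepoints = 2L), seed = 1
  )
  expect_equal(nrow(loso_split(co$phenotype)), 17)
})

test_that("metrics match the hand-enumerated confusion table and AUC", {
  # labels (1,1,0,0), probs (.9,.4,.6,.2): predictions at the 0.5 cut are
  # (1,0,1,0), so 2/4 correct overall, 1/2 in each class; of the four
  # HC-vs-ASD pairs, three are ranked correctly -> AUC 0.75
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$auc, 0.75)
  expect_equal(m$auc, bf_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)))

  perfect <- compute_metrics(c(1, 0, 1, 0), c(1, 0, 0.9, 0.1))
  expect_equal(unlist(perfect), c(1, 1, 1, 1), ignore_attr = TRUE)

  flat <- compute_metrics(c(1, 0, 1, 0), rep(0.5, 4))
  expect_equal(flat$auc, 0.5)

  one_class <- compute_metrics(c(1, 1), c(0.6, 0.4))
  expect_true(is.na(one_class$auc))
  expect_equal(one_class$accuracy, 0.5)
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  set.seed(40)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    probs <- round(runif(n), 2) # rounding forces ties
    expect_equal(
      compute_metrics(labels, probs)$auc, bf_auc(labels, probs),
      tolerance = 1e-12
    )
  }
})

test_that("experiment grid size, determinism and fold bookkeeping", {
  co <- tiny_cohort()
  cfg <- desk_cfg(hidden_units = 4, max_epochs = 5)
  res <- run_experiment(co,
    pipelines = "neg", thresholds = c(0.3, 0.4),
    cfg = cfg, n_repeats = 5, base_seed = 3
  )
  # 3 sites x 1 pipeline x 2 thresholds x 5 repeats
  expect_equal(nrow(res), 30)
  expect_true(all(res$n_test == 8))
  ok <- dplyr::select(res, "accuracy", "sensitivity", "specificity", "auc")
  expect_true(all(as.matrix(ok) >= 0 & as.matrix(ok) <= 1, na.rm = TRUE))

  res2 <- run_experiment(co,
    pipelines = "neg", thresholds = c(0.3, 0.4),
    cfg = cfg, n_repeats = 5, base_seed = 3
  )
  expect_identical(res, res2)
})

test_that("aggregation reproduces hand arithmetic and weighting", {
  # two sites (n = 10 and 30) with constant accuracies 0.5 and 0.7
  res <- tidyr::expand_grid(
    site = c("S1", "S2"), pipeline = "neg",
    threshold = c(0.2, 0.3), repetition = 1:2
  ) |>
    dplyr::mutate(
      n_test = ifelse(site == "S1", 10L, 30L),
      accuracy = ifelse(site == "S1", 0.5, 0.7),
      sensitivity = accuracy, specificity = accuracy, auc = accuracy
    )
  agg <- aggregate_results(res)
  acc <- dplyr::filter(agg, metric == "accuracy")
  expect_equal(acc$mean[acc$site == "S1"], 0.5)
  expect_equal(acc$sd[acc$site == "S1"], 0)
  expect_equal(acc$mean[acc$site == "Mean"], 0.6)
  expect_equal(acc$mean[acc$site == "Weighted Mean"], 0.65)

  # undefined AUCs are excluded and counted
  res$auc[res$site == "S1" & res$threshold == 0.2] <- NA
  agg2 <- aggregate_results(res)
  auc2 <- dplyr::filter(agg2, metric == "auc", site == "S1")
  expect_equal(auc2$mean, 0.5)
  expect_equal(auc2$n_undefined_auc, 2L)
})

test_that("no test-site information reaches the trained fold model", {
  co <- tiny_cohort(n_sites = 2, n_per_group = 3)
  ph <- co$phenotype
  # features for one pipeline/threshold
  conn <- lapply(co$ts, pearson_connectivity)
  graphs <- lapply(
    lapply(conn, apply_pipeline, mode = "neg"),
    proportional_threshold,
    p = 0.3
  )
  fm <- graph_feature_matrix(graphs)$values[ph$subject_id, ]
  te <- ph$site == "SITE01"
  Xtr <- fm[!te, ]
  Xte <- fm[te, ]
  y <- as.numeric(ph$diagnosis[!te] == "HC")
  cfg <- desk_cfg(hidden_units = 4, max_epochs = 5, seed = 2)

  fit_fold <- function(Xte_used) {
    std <- suppressWarnings(standardize(Xtr, Xte_used))
    train_mlp(std[[1]], y, cfg)
  }
  m1 <- fit_fold(Xte)
  m2 <- fit_fold(Xte + matrix(rnorm(length(Xte), sd = 10), nrow(Xte)))
  expect_identical(m1, m2)
})

test_that("autoplot renders the aggregate table", {
  res <- tidyr::expand_grid(
    site = c("S1", "S2"), pipeline = c("neg", "pos"),
    threshold = c(0.2, 0.3), repetition = 1:2
  ) |>
    dplyr::mutate(
      n_test = 10L, accuracy = runif(dplyr::n(), 0.4, 0.8),
      sensitivity = accuracy, specificity = accuracy, auc = accuracy
    )
  p <- ggplot2::autoplot(aggregate_results(res), metric = "auc")
  expect_s3_class(p, "ggplot")
})
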