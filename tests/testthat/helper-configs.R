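# small-data training config used across tests: modest width and dropout,
# conventional Adam moments for stable convergence at these sample sizes
desk_cfg <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(
      hidden_units = 16, dropout_rate = 0.2, l1_strength = 1e-4,
      l2_strength = 1e-3, learning_rate = 0.01, max_epochs = 60,
      conventional_betas = TRUE, seed = seed
    ),
    list(...)
  )
  do.call(mlp_config, args)
}

two_clouds <- function(n = 200, sep = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n / 2 * 2, mean = sep), n / 2, 2),
    matrix(rnorm(n / 2 * 2, mean = -sep), n / 2, 2)
  )
  list(X = standardize(X)[[1]], y = rep(c(1, 0), each = n / 2))
}

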