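#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the AUC-age regression coefficients
#'
#' @param x A `netsign_agefit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`; terms are named `intercept`, `age`, `age^2`, ...
#' @export
tidy.netsign_agefit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", c("age", paste0("age^", 2:9))[seq_len(x$degree)]),
    estimate = unname(sm[, 1]), std_error = unname(sm[, 2]),
    statistic = unname(sm[, 3]), p_value = unname(sm[, 4])
  )
}

#' One-row summary of the AUC-age regression
#'
#' @inheritParams tidy.netsign_agefit
#' @return Tibble with `r_squared`, `f_statistic`, `f_p_value`, `df`,
#'   `df_residual`, `n_sites`.
#' @export
glance.netsign_agefit <- function(x, ...) {
  sm <- summary(x$fit)
  f <- sm$fstatistic
  tibble::tibble(
    r_squared = sm$r.squared,
    f_statistic = unname(f[1]),
    f_p_value = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
    df = unname(f[2]), df_residual = unname(f[3]),
    n_sites = nrow(x$data)
  )
}

#' Tidy an MLP training history
#'
#' @param x A fitted `netsign_mlp`.
#' @param ... Unused.
#' @return The per-epoch history tibble (epoch, losses, learning rate).
#' @export
tidy.netsign_mlp <- function(x, ...) {
  if (is.null(x$history)) {
    stop("model has no training history (hand-set weights)")
  }
  x$history
}

#' One-row summary of a fitted MLP
#'
#' @inheritParams tidy.netsign_mlp
#' @return Tibble with parameter counts and final losses.
#' @export
glance.netsign_mlp <- function(x, ...) {
  n_par <- length(x$W1) + length(x$b1) + length(x$W2) + length(x$b2) +
    length(x$W3) + 1
  h <- x$history
  tibble::tibble(
    n_features = nrow(x$W1), hidden_units = ncol(x$W1),
    n_parameters = n_par,
    epochs = if (is.null(h)) NA_integer_ else max(h$epoch),
    final_train_loss = if (is.null(h)) NA_real_ else
      h$train_loss[nrow(h)],
    final_val_loss = if (is.null(h)) NA_real_ else h$val_loss[nrow(h)]
  )
}
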