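#' Configuration of the regularized multilayer perceptron
#'
#' Two hidden layers of rectified linear units; the first hidden layer is
#' L1-regularized (driving implicit feature selection), the second is
#' L2-regularized, and dropout is applied after each hidden layer. The output
#' neuron is sigmoid-activated, trained with binary cross-entropy and Adam.
#' The Adam moment-decay defaults are `beta1 = 0.99`, `beta2 = 0.01`;
#' `conventional_betas = TRUE` restores the customary (0.9, 0.999) pair for
#' sensitivity checks. The learning rate is halved whenever the validation
#' loss (on a stratified random hold-out of the training subjects) fails to
#' improve for `patience` consecutive epochs; training stops early after
#' `max_decays` decays without improvement.
#'
#' @param hidden_units Units in each hidden layer (default 512).
#' @param l1_strength,l2_strength Regularization strengths for the first and
#'   second hidden-layer weight matrices.
#' @param dropout_rate Dropout probability after each hidden layer, in [0, 1).
#' @param adam_beta1,adam_beta2 Adam moment decays, each in (0, 1).
#' @param conventional_betas If `TRUE`, override the betas with (0.9, 0.999).
#' @param learning_rate Initial Adam step size.
#' @param lr_decay_factor Multiplier applied on a validation-loss plateau.
#' @param validation_fraction Fraction of training subjects withheld for the
#'   schedule, in (0, 1).
#' @param max_epochs,batch_size,patience,max_decays Training-loop counts.
#' @param seed Integer seed controlling initialization, the validation split,
#'   minibatch order and dropout masks.
#' @return A `netsign_mlp_config` list.
#' @export
mlp_config <- function(hidden_units = 512L, l1_strength = 1e-3,
                       l2_strength = 1e-2, dropout_rate = 0.7,
                       adam_beta1 = 0.99, adam_beta2 = 0.01,
                       conventional_betas = FALSE,
                       learning_rate = 2e-4, lr_decay_factor = 0.5,
                       validation_fraction = 0.10, max_epochs = 200L,
                       batch_size = 32L, patience = 5L, max_decays = 3L,
                       seed = 1L) {
  if (conventional_betas) {
    adam_beta1 <- 0.9
    adam_beta2 <- 0.999
  }
  stopifnot(
    hidden_units >= 1, l1_strength >= 0, l2_strength >= 0,
    dropout_rate >= 0, dropout_rate < 1,
    adam_beta1 > 0, adam_beta1 < 1, adam_beta2 > 0, adam_beta2 < 1,
    learning_rate > 0, lr_decay_factor > 0, lr_decay_factor <= 1,
    validation_fraction > 0, validation_fraction < 1,
    max_epochs >= 1, batch_size >= 1, patience >= 1, max_decays >= 0
  )
  structure(
    list(
      hidden_units = as.integer(hidden_units), l1_strength = l1_strength,
      l2_strength = l2_strength, dropout_rate = dropout_rate,
      adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
      learning_rate = learning_rate, lr_decay_factor = lr_decay_factor,
      validation_fraction = validation_fraction,
      max_epochs = as.integer(max_epochs), batch_size = as.integer(batch_size),
      patience = as.integer(patience), max_decays = as.integer(max_decays),
      seed = as.integer(seed)
    ),
    class = "netsign_mlp_config"
  )
}

#' Build an MLP model object from explicit weights
#'
#' Mostly useful for testing the forward pass against hand-computed values.
#'
#' @param W1,b1 Input-to-hidden-1 weights (D x H) and bias (length H).
#' @param W2,b2 Hidden-1-to-hidden-2 weights (H x H2) and bias.
#' @param W3,b3 Hidden-2-to-output weights (H2 x 1) and bias (length 1).
#' @param history Optional training-history tibble.
#' @return A `netsign_mlp`.
#' @export
mlp_model <- function(W1, b1, W2, b2, W3, b3, history = NULL) {
  W3 <- matrix(W3, ncol = 1)
  stopifnot(
    ncol(W1) == length(b1), nrow(W2) == ncol(W1), ncol(W2) == length(b2),
    nrow(W3) == ncol(W2), length(b3) == 1
  )
  structure(
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3,
         history = history),
    class = "netsign_mlp"
  )
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass; dropout masks (already inverted-scaled) only during training
mlp_forward <- function(m, X, drop1 = NULL, drop2 = NULL) {
  H1 <- relu(sweep(X %*% m$W1, 2, m$b1, "+"))
  if (!is.null(drop1)) H1 <- H1 * drop1
  H2 <- relu(sweep(H1 %*% m$W2, 2, m$b2, "+"))
  if (!is.null(drop2)) H2 <- H2 * drop2
  p <- sigmoid(as.numeric(H2 %*% m$W3) + m$b3)
  list(H1 = H1, H2 = H2, p = p)
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

penalty <- function(m, cfg) {
  cfg$l1_strength * sum(abs(m$W1)) + cfg$l2_strength * sum(m$W2^2)
}

# stratified index split: validation gets ceil(frac * n_class) per class
validation_split <- function(y, frac) {
  val <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_val <- max(1L, floor(frac * length(idx) + 0.5))
    if (n_val >= length(idx)) n_val <- length(idx) - 1L
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

#' Train the regularized MLP
#'
#' Minimizes binary cross-entropy plus the L1 penalty on the first hidden
#' layer and L2 on the second, with dropout after each hidden layer, Adam
#' updates, and plateau-based learning-rate decay monitored on a stratified
#' validation split of the training subjects. Labels follow the convention
#' healthy control = 1, case = 0. Training is deterministic given
#' `(cfg$seed, data)`.
#'
#' @param X Standardized feature matrix (subjects x features), all finite.
#' @param y Numeric 0/1 labels, both classes present.
#' @param cfg An [mlp_config()].
#' @return A fitted `netsign_mlp` with a `history` tibble (epoch, training
#'   loss, validation loss, learning rate).
#' @export
train_mlp <- function(X, y, cfg = mlp_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (!all(is.finite(X))) stop("non-finite feature values")
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  withr::local_seed(cfg$seed)

  D <- ncol(X)
  H <- cfg$hidden_units
  init <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  }
  m <- list(
    W1 = init(D, H), b1 = rep(0, H),
    W2 = init(H, H), b2 = rep(0, H),
    W3 = init(H, 1), b3 = 0
  )
  adam_m <- lapply(m, function(w) w * 0)
  adam_v <- lapply(m, function(w) w * 0)
  step <- 0L

  val_idx <- validation_split(y, cfg$validation_fraction)
  if (length(val_idx) == 0) val_idx <- seq_along(y) # degenerate tiny input
  tr_idx <- setdiff(seq_along(y), val_idx)
  if (length(tr_idx) == 0) tr_idx <- seq_along(y)
  Xv <- X[val_idx, , drop = FALSE]
  yv <- y[val_idx]
  Xt <- X[tr_idx, , drop = FALSE]
  yt <- y[tr_idx]

  lr <- cfg$learning_rate
  best_val <- Inf
  stall <- 0L
  n_decays <- 0L
  hist <- vector("list", cfg$max_epochs)
  keep <- 1 - cfg$dropout_rate

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(length(yt))
    starts <- seq(1, length(yt), by = cfg$batch_size)
    for (s in starts) {
      b <- ord[s:min(s + cfg$batch_size - 1L, length(yt))]
      Xb <- Xt[b, , drop = FALSE]
      yb <- yt[b]
      nb <- length(b)
      d1 <- matrix(stats::rbinom(nb * H, 1, keep), nb, H) / keep
      d2 <- matrix(stats::rbinom(nb * H, 1, keep), nb, H) / keep
      fw <- mlp_forward(m, Xb, d1, d2)
      # backprop of mean BCE: d loss / d logit = (p - y) / n
      dz3 <- matrix((fw$p - yb) / nb, ncol = 1)
      g <- list(
        W3 = t(fw$H2) %*% dz3, b3 = sum(dz3)
      )
      dH2 <- (dz3 %*% t(m$W3)) * d2 * (fw$H2 > 0)
      g$W2 <- t(fw$H1) %*% dH2 + 2 * cfg$l2_strength * m$W2
      g$b2 <- colSums(dH2)
      dH1 <- (dH2 %*% t(m$W2)) * d1 * (fw$H1 > 0)
      g$W1 <- t(Xb) %*% dH1 + cfg$l1_strength * sign(m$W1)
      g$b1 <- colSums(dH1)

      step <- step + 1L
      for (nm in names(m)) {
        adam_m[[nm]] <- cfg$adam_beta1 * adam_m[[nm]] +
          (1 - cfg$adam_beta1) * g[[nm]]
        adam_v[[nm]] <- cfg$adam_beta2 * adam_v[[nm]] +
          (1 - cfg$adam_beta2) * g[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - cfg$adam_beta1^step)
        vhat <- adam_v[[nm]] / (1 - cfg$adam_beta2^step)
        m[[nm]] <- m[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
    train_loss <- bce_loss(mlp_forward(m, Xt)$p, yt) + penalty(m, cfg)
    val_loss <- bce_loss(mlp_forward(m, Xv)$p, yv)
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = train_loss, val_loss = val_loss,
      learning_rate = lr
    )
    if (val_loss < best_val - 1e-4) {
      best_val <- val_loss
      stall <- 0L
      n_decays <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) {
        n_decays <- n_decays + 1L
        if (n_decays > cfg$max_decays) break
        lr <- lr * cfg$lr_decay_factor
        stall <- 0L
      }
    }
  }
  mlp_model(m$W1, m$b1, m$W2, m$b2, m$W3, m$b3,
    history = dplyr::bind_rows(hist)
  )
}

#' Predict class-1 probabilities
#'
#' Dropout is disabled at inference; the output is the sigmoid activation in
#' (0, 1) for each subject.
#'
#' @param model A fitted `netsign_mlp`.
#' @param X Feature matrix with the same columns the model was trained on.
#' @return Numeric vector of probabilities.
#' @export
predict_mlp <- function(model, X) {
  stopifnot(is.matrix(X))
  if (ncol(X) != nrow(model$W1)) {
    stop(sprintf(
      "feature dimension mismatch: model expects %d, got %d",
      nrow(model$W1), ncol(X)
    ))
  }
  mlp_forward(model, X)$p
}

#' @export
print.netsign_mlp <- function(x, ...) {
  cat(sprintf(
    "<netsign_mlp> %d-%d-%d-1, %s\n",
    nrow(x$W1), ncol(x$W1), ncol(x$W2),
    if (is.null(x$history)) "hand-set weights" else
      sprintf("trained %d epochs", max(x$history$epoch))
  ))
  invisible(x)
}
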