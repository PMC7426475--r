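#' Assemble the graph-feature vector of one subject's binary graph
#'
#' Concatenates, in fixed documented order, seven node-level metrics over the
#' N nodes — degree, clustering coefficient, local efficiency, betweenness
#' centrality, eigenvector centrality, participation coefficient,
#' within-module z-score — followed by four global metrics: characteristic
#' path length, global efficiency, transitivity, assortativity. The vector
#' length is therefore `7 N + 4`; for a 200-region parcellation that is
#' 1404 features.
#'
#' @param g A `netsign_graph`.
#' @param seed Seed for the community-detection sweep feeding the
#'   participation coefficient and within-module z-score.
#' @return Named numeric vector of length `7 * n_nodes + 4`.
#' @export
assemble_graph_features <- function(g, seed = 1L) {
  n <- g$n_nodes
  part <- detect_communities(g, seed = seed)
  glob <- global_metrics(g)
  node_blocks <- list(
    degree = node_degree(g),
    clustering = clustering_coefficient(g),
    local_efficiency = local_efficiency(g),
    betweenness = betweenness_centrality(g),
    eigenvector = eigenvector_centrality(g),
    participation = participation_coefficient(g, part$membership),
    within_module_z = within_module_zscore(g, part$membership)
  )
  out <- c(
    unlist(lapply(names(node_blocks), function(nm) {
      stats::setNames(node_blocks[[nm]], paste0(nm, "_", seq_len(n)))
    })),
    cpl = glob$cpl, global_efficiency = glob$global_efficiency,
    transitivity = glob$transitivity, assortativity = glob$assortativity
  )
  # disconnected graphs can have no finite CPL; keep the matrix rectangular
  out[!is.finite(out)] <- 0
  out
}

#' Feature matrix for a set of subjects at one (pipeline, threshold) cell
#'
#' @param graphs Named list of `netsign_graph`s (names = subject ids).
#' @param seeds Integer vector of community-detection seeds, one per subject
#'   (recycled).
#' @return A `netsign_features` list: `values` (subjects x F matrix),
#'   `feature_names`, `subject_ids`.
#' @export
graph_feature_matrix <- function(graphs, seeds = seq_along(graphs)) {
  seeds <- rep_len(seeds, length(graphs))
  rows <- purrr::map2(graphs, seeds, ~ assemble_graph_features(.x, seed = .y))
  values <- do.call(rbind, rows)
  rownames(values) <- names(graphs)
  structure(
    list(
      values = values, feature_names = colnames(values),
      subject_ids = names(graphs)
    ),
    class = "netsign_features"
  )
}

# vectorize the strict upper triangle of a connectivity matrix
vec_upper <- function(C) {
  C <- unclass(C)
  C[upper.tri(C)]
}

#' Principal components of vectorized connectivity matrices
#'
#' Fits PCA on the strict upper triangles of the training subjects'
#' (unaltered, signed) correlation matrices; `transform_pca` projects any
#' subject onto the fitted components. `K` is truncated to the feasible rank
#' `min(n_train - 1, D)` with a warning.
#'
#' @param connectivities List of connectivity matrices (training subjects).
#' @param K Number of components requested (default 600).
#' @return `fit_pca`: a `netsign_pca` with orthonormal `loadings` (D x K),
#'   `center` (length D) and `K`. `transform_pca`: length-K numeric vector.
#' @export
fit_pca <- function(connectivities, K = 600L) {
  if (K <= 0) stop("K must be positive")
  if (length(connectivities) < 2) stop("need at least 2 training subjects")
  X <- do.call(rbind, lapply(connectivities, vec_upper))
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  k_max <- min(nrow(X) - 1L, ncol(X))
  if (K > k_max) {
    warning(sprintf("K truncated from %d to feasible rank %d", K, k_max))
    K <- k_max
  }
  sv <- svd(Xc, nu = 0, nv = K)
  structure(
    list(loadings = sv$v, center = center, K = as.integer(K)),
    class = "netsign_pca"
  )
}

#' @rdname fit_pca
#' @param model A fitted `netsign_pca`.
#' @param C One connectivity matrix.
#' @export
transform_pca <- function(model, C) {
  x <- vec_upper(C) - model$center
  as.numeric(x %*% model$loadings)
}

#' Train-fold standardization
#'
#' Estimates per-feature mean and population SD on the training matrix only
#' and applies the same affine map to every matrix passed. Zero-variance
#' features map to 0 everywhere (with a warning), keeping the matrices
#' finite.
#'
#' @param train Numeric matrix (subjects x features) the scaler is fit on.
#' @param ... Further matrices with the same columns to transform.
#' @return A list of standardized matrices, the training matrix first.
#' @export
standardize <- function(train, ...) {
  stopifnot(is.matrix(train), nrow(train) >= 1)
  mu <- colMeans(train)
  sdp <- sqrt(colMeans(sweep(train, 2, mu)^2))
  dead <- sdp == 0
  if (any(dead)) {
    warning(sprintf("%d zero-variance feature(s) mapped to 0", sum(dead)))
    sdp[dead] <- 1
  }
  apply_one <- function(M) {
    Z <- sweep(sweep(M, 2, mu), 2, sdp, "/")
    Z[, dead] <- 0
    Z
  }
  lapply(c(list(train), list(...)), apply_one)
}
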