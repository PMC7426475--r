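#' Pearson connectivity matrix from ROI time series
#'
#' Correlates every pair of regional time series with Pearson's r, producing
#' the symmetric connectivity matrix that the sign-handling pipelines start
#' from. The diagonal is set to exactly 1.
#'
#' @param ts Numeric matrix, regions x time points (rows are ROIs). Row names,
#'   if present, are kept as ROI labels.
#' @return An N x N correlation matrix of class `netsign_connectivity` with
#'   ROI labels as dimnames.
#' @examples
#' ts <- matrix(rnorm(5 * 100), nrow = 5)
#' C <- pearson_connectivity(ts)
#' @export
pearson_connectivity <- function(ts) {
  stopifnot(is.matrix(ts), is.numeric(ts))
  if (ncol(ts) < 2) stop("need at least 2 time points to correlate")
  labels <- rownames(ts)
  if (is.null(labels)) labels <- paste0("ROI", seq_len(nrow(ts)))
  v <- apply(ts, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance ROI(s): ", paste(labels[v == 0], collapse = ", "))
  }
  C <- stats::cor(t(ts))
  diag(C) <- 1
  dimnames(C) <- list(labels, labels)
  class(C) <- c("netsign_connectivity", class(C))
  C
}

#' Apply a sign-handling pipeline to a connectivity matrix
#'
#' The three pipelines differ only in how they treat the sign of a
#' correlation before thresholding: `"pos"` keeps positive entries as-is and
#' drops the rest; `"neg"` keeps negative entries with their sign flipped
#' (so strong anti-correlations become strong weights); `"abs"` keeps the
#' magnitude of every nonzero entry. Exact zeros are treated as absent in all
#' three modes, and the diagonal is always absent.
#'
#' @param C Connectivity matrix from [pearson_connectivity()].
#' @param mode One of `"pos"`, `"neg"`, `"abs"`.
#' @return N x N weight matrix with `NA` marking absent entries; all retained
#'   weights are strictly positive.
#' @export
apply_pipeline <- function(C, mode = c("pos", "neg", "abs")) {
  mode <- match.arg(mode)
  W <- unclass(C)
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  W <- switch(mode,
    pos = ifelse(W > 0, W, NA_real_),
    neg = ifelse(W < 0, -W, NA_real_),
    abs = ifelse(W != 0, abs(W), NA_real_)
  )
  diag(W) <- NA_real_
  W
}

#' Default proportional threshold grid
#'
#' Proportions of strongest connections retained: 20% to 50% in 2% steps
#' (16 values).
#'
#' @return Numeric vector of proportions.
#' @export
threshold_grid <- function() seq(0.20, 0.50, by = 0.02)

# round half away from zero; base round() is banker's rounding
round_half_up <- function(x) floor(x + 0.5)

#' Proportional thresholding to a binary graph
#'
#' Keeps the top `round(p * N(N-1)/2)` strongest retained weights as edges,
#' where the denominator is the count of all node pairs, not only the
#' sign-retained ones, so a given `p` means the same target density for all
#' pipelines. Ties at the cut are broken by lexicographic (i, j) order; `round`
#' is half-away-from-zero. If sign filtering left fewer weights than the
#' target, all retained pairs become edges and a warning is raised.
#'
#' @param W Weight matrix from [apply_pipeline()] (`NA` = absent).
#' @param p Proportion of strongest connections to keep, in (0, 1].
#' @return A `netsign_graph`: list with `n_nodes` and an `edges` matrix
#'   (two columns, 1-based node indices, i < j).
#' @export
proportional_threshold <- function(W, p) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p > 1) {
    stop("p must be a single proportion in (0, 1]")
  }
  n <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[upper.tri(W)]
  keep <- !is.na(w)
  ut <- ut[keep, , drop = FALSE]
  w <- w[keep]
  k <- round_half_up(p * n * (n - 1) / 2)
  if (length(w) < k) {
    warning(sprintf(
      "only %d of the %d requested edges available after sign filtering",
      length(w), k
    ))
    k <- length(w)
  }
  ord <- order(-w, ut[, 1], ut[, 2])
  sel <- ord[seq_len(k)]
  edges <- ut[sel, , drop = FALSE]
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("i", "j"))
  structure(list(n_nodes = n, edges = edges), class = "netsign_graph")
}

#' @export
print.netsign_graph <- function(x, ...) {
  cat(sprintf(
    "<netsign_graph> %d nodes, %d edges (density %.3f)\n",
    x$n_nodes, nrow(x$edges),
    nrow(x$edges) / (x$n_nodes * (x$n_nodes - 1) / 2)
  ))
  invisible(x)
}

#' Build a binary graph directly from a connectivity matrix
#'
#' Convenience wrapper: sign-handling pipeline followed by proportional
#' thresholding.
#'
#' @inheritParams apply_pipeline
#' @inheritParams proportional_threshold
#' @return A `netsign_graph`.
#' @export
connectivity_graph <- function(C, mode, p) {
  proportional_threshold(apply_pipeline(C, mode), p)
}

# dense adjacency matrix of a netsign_graph
adjacency <- function(g) {
  A <- matrix(0L, g$n_nodes, g$n_nodes)
  if (nrow(g$edges) > 0) {
    A[g$edges] <- 1L
    A[g$edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  A
}

# igraph view of a netsign_graph (isolated nodes preserved)
as_igraph <- function(g) {
  igraph::make_graph(as.vector(t(g$edges)), n = g$n_nodes, directed = FALSE)
}

#' Write / read a binary graph as an edge-list text file
#'
#' Two whitespace-separated columns of 0-based node indices, one edge per
#' line, preceded by a comment line recording the node count.
#'
#' @param g A `netsign_graph`.
#' @param path File path.
#' @return `write_graph_edgelist` returns `path` invisibly;
#'   `read_graph_edgelist` returns a `netsign_graph`.
#' @export
write_graph_edgelist <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nodes: %d", g$n_nodes), con)
  utils::write.table(g$edges - 1L, con,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_graph_edgelist
#' @export
read_graph_edgelist <- function(path) {
  header <- readLines(path, n = 1)
  n <- as.integer(sub("# nodes: ", "", header))
  edges <- as.matrix(utils::read.table(path, comment.char = "#")) + 1L
  dimnames(edges) <- list(NULL, c("i", "j"))
  structure(list(n_nodes = n, edges = edges), class = "netsign_graph")
}
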