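#' Node and global measures of binary brain graphs
#'
#' The feature set follows the brain-connectivity-toolbox families: integration
#' (characteristic path length, global and local efficiency), segregation
#' (clustering coefficient, transitivity), centrality (degree, betweenness,
#' eigenvector centrality, participation coefficient, within-module degree
#' z-score) and resilience (degree assortativity). All measures are defined on
#' undirected, unweighted simple graphs; degenerate cases resolve to documented
#' sentinels so feature matrices stay finite and rectangular.
#'
#' @name graph_metrics
NULL

#' @describeIn graph_metrics Degree of each node.
#' @param g A `netsign_graph`.
#' @return Numeric vector of length `n_nodes` (node metrics) or a scalar
#'   (global metrics).
#' @export
node_degree <- function(g) {
  d <- tabulate(g$edges, nbins = g$n_nodes)
  as.numeric(d)
}

#' @describeIn graph_metrics Per-node clustering coefficient
#'   `2 * triangles_i / (k_i (k_i - 1))`, zero when the degree is below 2.
#' @export
clustering_coefficient <- function(g) {
  cc <- igraph::transitivity(as_igraph(g), type = "local", isolates = "zero")
  as.numeric(cc)
}

#' @describeIn graph_metrics Global transitivity, `3 * triangles / triads`;
#'   zero for triad-free graphs.
#' @export
graph_transitivity <- function(g) {
  tr <- igraph::transitivity(as_igraph(g), type = "global")
  if (is.nan(tr)) tr <- 0
  tr
}

#' @describeIn graph_metrics Characteristic path length (mean shortest-path
#'   distance over reachable ordered pairs) and global efficiency (mean inverse
#'   distance over all ordered pairs, unreachable contributing 0). Returned as
#'   a named list with elements `cpl` and `global_efficiency`.
#' @export
shortest_path_metrics <- function(g) {
  if (g$n_nodes < 2) stop("graph must have at least 2 nodes")
  D <- igraph::distances(as_igraph(g))
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  cpl <- if (any(finite)) mean(off[finite]) else NaN
  eff <- mean(ifelse(finite, 1 / off, 0))
  list(cpl = cpl, global_efficiency = eff)
}

#' @describeIn graph_metrics Local efficiency: for each node, the global
#'   efficiency of the subgraph induced on its neighbours; 0 when the degree
#'   is below 2.
#' @export
local_efficiency <- function(g) {
  A <- adjacency(g)
  vapply(seq_len(g$n_nodes), function(i) {
    nb <- which(A[i, ] == 1L)
    if (length(nb) < 2) return(0)
    sub <- A[nb, nb, drop = FALSE]
    ig <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    D <- igraph::distances(ig)
    off <- D[row(D) != col(D)]
    mean(ifelse(is.finite(off), 1 / off, 0))
  }, numeric(1))
}

#' @describeIn graph_metrics Unnormalized shortest-path betweenness
#'   (Brandes), endpoints excluded; each unordered pair counted once.
#' @export
betweenness_centrality <- function(g) {
  as.numeric(igraph::betweenness(as_igraph(g), directed = FALSE))
}

#' @describeIn graph_metrics Eigenvector centrality: nonnegative principal
#'   eigenvector of the adjacency matrix restricted to the largest connected
#'   component, scaled to unit Euclidean norm, zero off that component. Ties
#'   for largest component break on the lowest contained node index.
#' @export
eigenvector_centrality <- function(g) {
  A <- adjacency(g)
  comp <- igraph::components(as_igraph(g))
  sizes <- comp$csize
  big <- which(sizes == max(sizes))[1]
  idx <- which(comp$membership == big)
  out <- numeric(g$n_nodes)
  if (length(idx) == 1) {
    out[idx] <- 1
    return(out)
  }
  ev <- eigen(A[idx, idx], symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  out[idx] <- v / sqrt(sum(v^2))
  out
}

#' Community structure by modularity maximization
#'
#' Runs Louvain modularity maximization with a fixed RNG seed so that feature
#' extraction is reproducible; isolated nodes form singleton modules.
#'
#' @param g A `netsign_graph`.
#' @param seed Integer seed for the (stochastic) Louvain sweep.
#' @return List with `membership` (integer module id per node) and
#'   `modularity` (Q of the returned partition).
#' @export
detect_communities <- function(g, seed = 1L) {
  ig <- as_igraph(g)
  cl <- withr::with_seed(seed, igraph::cluster_louvain(ig))
  membership <- as.integer(igraph::membership(cl))
  q <- if (nrow(g$edges) == 0) 0 else
    igraph::modularity(ig, membership)
  list(membership = membership, modularity = q)
}

#' @describeIn graph_metrics Participation coefficient
#'   `1 - sum_s (k_is / k_i)^2` for partition `membership`; 0 for isolated
#'   nodes.
#' @param membership Integer module id per node.
#' @export
participation_coefficient <- function(g, membership) {
  stopifnot(length(membership) == g$n_nodes)
  A <- adjacency(g)
  k <- rowSums(A)
  vapply(seq_len(g$n_nodes), function(i) {
    if (k[i] == 0) return(0)
    kis <- tapply(A[i, ], membership, sum)
    1 - sum((kis / k[i])^2)
  }, numeric(1))
}

#' @describeIn graph_metrics Within-module degree z-score: a node's
#'   intra-module degree standardized against its module's mean and
#'   population SD of intra-module degrees; 0 when that SD is 0.
#' @export
within_module_zscore <- function(g, membership) {
  stopifnot(length(membership) == g$n_nodes)
  A <- adjacency(g)
  z <- numeric(g$n_nodes)
  for (m in unique(membership)) {
    idx <- which(membership == m)
    kin <- rowSums(A[idx, idx, drop = FALSE])
    mu <- mean(kin)
    sdp <- sqrt(mean((kin - mu)^2))
    z[idx] <- if (sdp > 0) (kin - mu) / sdp else 0
  }
  z
}

#' @describeIn graph_metrics Degree assortativity: Pearson correlation of
#'   endpoint degrees over both orientations of every edge. Regular graphs
#'   (zero endpoint-degree variance) return the sentinel 0 with a warning.
#' @export
graph_assortativity <- function(g) {
  if (nrow(g$edges) == 0) stop("assortativity needs at least one edge")
  k <- node_degree(g)
  x <- c(k[g$edges[, 1]], k[g$edges[, 2]])
  y <- c(k[g$edges[, 2]], k[g$edges[, 1]])
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("assortativity undefined on a regular graph; returning 0")
    return(0)
  }
  stats::cor(x, y)
}

#' All global metrics of a graph
#'
#' @param g A `netsign_graph`.
#' @return A one-row tibble with columns `cpl`, `global_efficiency`,
#'   `transitivity`, `assortativity`.
#' @export
global_metrics <- function(g) {
  sp <- shortest_path_metrics(g)
  assort <- if (nrow(g$edges) == 0) 0 else
    suppressWarnings(graph_assortativity(g))
  tibble::tibble(
    cpl = sp$cpl,
    global_efficiency = sp$global_efficiency,
    transitivity = graph_transitivity(g),
    assortativity = assort
  )
}
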