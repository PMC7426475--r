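p3 <- function() graph_from_adj(rbind(
  c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)
))

test_that("analytic values on canonical small graphs", {
  k3 <- graph_from_adj(matrix(1, 3, 3) - diag(3))
  k4 <- graph_from_adj(matrix(1, 4, 4) - diag(4))
  p4 <- graph_from_adj(rbind(
    c(0, 1, 0, 0), c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 0)
  ))
  star5 <- graph_from_adj(rbind(
    c(0, 1, 1, 1, 1), c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0),
    c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0)
  ))

  expect_equal(node_degree(star5), c(4, 1, 1, 1, 1))
  expect_equal(clustering_coefficient(k3), rep(1, 3))
  expect_equal(graph_transitivity(k3), 1)
  expect_equal(clustering_coefficient(p4), rep(0, 4))
  expect_equal(graph_transitivity(p4), 0)

  sp3 <- shortest_path_metrics(p3())
  expect_equal(sp3$cpl, 4 / 3)
  expect_equal(sp3$global_efficiency, 5 / 6)
  sp4 <- shortest_path_metrics(k4)
  expect_equal(sp4$cpl, 1)
  expect_equal(sp4$global_efficiency, 1)

  # two disjoint edges: CPL over finite pairs only, efficiency counts all
  de <- graph_from_adj(rbind(
    c(0, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 0, 1), c(0, 0, 1, 0)
  ))
  spd <- shortest_path_metrics(de)
  expect_equal(spd$cpl, 1)
  expect_equal(spd$global_efficiency, 4 / 12)

  expect_equal(local_efficiency(k4), rep(1, 4))
  expect_equal(local_efficiency(star5), rep(0, 5))

  expect_equal(betweenness_centrality(p3()), c(0, 1, 0))
  expect_equal(betweenness_centrality(star5), c(6, 0, 0, 0, 0))

  # C5 is regular: uniform eigenvector centrality
  c5 <- graph_from_adj(rbind(
    c(0, 1, 0, 0, 1), c(1, 0, 1, 0, 0), c(0, 1, 0, 1, 0),
    c(0, 0, 1, 0, 1), c(1, 0, 0, 1, 0)
  ))
  expect_equal(eigenvector_centrality(c5), rep(1 / sqrt(5), 5))
  # K3 plus isolate: equal mass on the triangle, zero on the isolate
  k3i <- graph_from_adj(rbind(
    c(0, 1, 1, 0), c(1, 0, 1, 0), c(1, 1, 0, 0), c(0, 0, 0, 0)
  ))
  expect_equal(eigenvector_centrality(k3i), c(rep(1 / sqrt(3), 3), 0))

  expect_equal(graph_assortativity(star5), -1)
  expect_warning(a <- graph_assortativity(de), "regular")
  expect_equal(a, 0)
  expect_error(graph_assortativity(graph_from_adj(matrix(0, 3, 3))), "edge")

  expect_equal(node_degree(graph_from_adj(matrix(0, 4, 4))), rep(0, 4))
  expect_error(shortest_path_metrics(graph_from_adj(matrix(0, 1, 1))))
})

test_that("community detection recovers planted clique structure", {
  # two disjoint K4 cliques: optimal partition is the cliques, Q = 0.5
  A <- matrix(0L, 8, 8)
  A[1:4, 1:4] <- 1L
  A[5:8, 5:8] <- 1L
  diag(A) <- 0L
  part <- detect_communities(graph_from_adj(A), seed = 3)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(length(unique(part$membership[1:4])), 1)
  expect_equal(length(unique(part$membership[5:8])), 1)
  expect_equal(part$modularity, 0.5)
  expect_equal(part$modularity, bf_modularity(A, part$membership))

  # complete graph: Q = 0 for the single-module partition
  k5 <- graph_from_adj(matrix(1, 5, 5) - diag(5))
  expect_equal(detect_communities(k5, seed = 1)$modularity, 0, tolerance = 1e-12)

  # ring of 4 K4 cliques with single bridges -> the 4 cliques recovered
  A <- matrix(0L, 16, 16)
  for (b in 0:3) A[b * 4 + 1:4, b * 4 + 1:4] <- 1L
  diag(A) <- 0L
  bridges <- rbind(c(4, 5), c(8, 9), c(12, 13), c(16, 1))
  A[bridges] <- 1L
  A[bridges[, c(2, 1)]] <- 1L
  part <- detect_communities(graph_from_adj(A), seed = 5)
  expect_equal(length(unique(part$membership)), 4)
  for (b in 0:3) {
    expect_equal(length(unique(part$membership[b * 4 + 1:4])), 1)
  }
})

test_that("participation and within-module z match hand values", {
  # path 1-2-3 with nodes 1,2 in module 1 and 3 in module 2:
  # node 2 has degree 2 split evenly across modules -> P = 0.5
  memb <- c(1, 1, 2)
  expect_equal(participation_coefficient(p3(), memb), c(0, 0.5, 0))
  # all edges within own module -> P = 0
  k3 <- graph_from_adj(matrix(1, 3, 3) - diag(3))
  expect_equal(participation_coefficient(k3, c(1, 1, 1)), c(0, 0, 0))

  # single-module P3: within-degrees {1,2,1}, population sd sqrt(2/9)
  z <- within_module_zscore(p3(), c(1, 1, 1))
  expect_equal(z, c(-1 / sqrt(2), sqrt(2), -1 / sqrt(2)))
  # clique module: sd = 0 sentinel
  expect_equal(within_module_zscore(k3, c(1, 1, 1)), c(0, 0, 0))
})

test_that("all metrics agree with brute-force oracles on random graphs", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    A <- rand_graph(n, runif(1, 0.2, 0.8))
    g <- graph_from_adj(A)
    expect_equal(node_degree(g), rowSums(A), ignore_attr = TRUE)
    expect_equal(clustering_coefficient(g), bf_clustering(A),
      tolerance = 1e-10
    )
    expect_equal(graph_transitivity(g), bf_transitivity(A), tolerance = 1e-10)
    sp <- shortest_path_metrics(g)
    bf <- bf_cpl_eff(A)
    if (is.finite(bf$cpl)) expect_equal(sp$cpl, bf$cpl, tolerance = 1e-10)
    expect_equal(sp$global_efficiency, bf$eff, tolerance = 1e-10)
    expect_equal(local_efficiency(g), bf_local_eff(A), tolerance = 1e-10)
    expect_equal(betweenness_centrality(g), bf_betweenness(A),
      tolerance = 1e-10
    )
    expect_equal(eigenvector_centrality(g), bf_eigencent(A),
      tolerance = 1e-6
    )
    memb <- sample(1:3, n, replace = TRUE)
    expect_equal(participation_coefficient(g, memb),
      bf_participation(A, memb),
      tolerance = 1e-10
    )
    expect_equal(within_module_zscore(g, memb), bf_within_z(A, memb),
      tolerance = 1e-10
    )
    if (sum(A) > 0) {
      bfa <- bf_assortativity(A)
      got <- suppressWarnings(graph_assortativity(g))
      if (is.na(bfa)) expect_equal(got, 0) else
        expect_equal(got, bfa, tolerance = 1e-10)
    }
  }
})

test_that("node metrics are invariant under node relabelling", {
  set.seed(99)
  for (rep in 1:5) {
    A <- rand_graph(8, 0.5)
    perm <- sample(8)
    Ap <- A[perm, perm] # node i of Ap is node perm[i] of A
    g <- graph_from_adj(A)
    gp <- graph_from_adj(Ap)
    expect_equal(node_degree(gp), node_degree(g)[perm])
    expect_equal(clustering_coefficient(gp), clustering_coefficient(g)[perm])
    expect_equal(betweenness_centrality(gp),
      betweenness_centrality(g)[perm],
      tolerance = 1e-10
    )
    memb <- sample(1:2, 8, replace = TRUE)
    expect_equal(
      within_module_zscore(gp, memb[perm]),
      within_module_zscore(g, memb)[perm]
    )
    expect_equal(graph_transitivity(gp), graph_transitivity(g))
  }
})

test_that("adding an edge never hurts efficiency nor helps CPL on fixed pairs", {
  set.seed(7)
  for (rep in 1:5) {
    A <- rand_graph(8, 0.4)
    miss <- which(upper.tri(A) & A == 0L, arr.ind = TRUE)
    if (nrow(miss) == 0) next
    pick <- miss[sample(nrow(miss), 1), ]
    A2 <- A
    A2[pick[1], pick[2]] <- A2[pick[2], pick[1]] <- 1L
    e1 <- shortest_path_metrics(graph_from_adj(A))$global_efficiency
    e2 <- shortest_path_metrics(graph_from_adj(A2))$global_efficiency
    expect_gte(e2, e1)
    # CPL restricted to the pairs already reachable before the edge
    D1 <- bf_distances(A)
    D2 <- bf_distances(A2)
    reach <- is.finite(D1) & row(D1) != col(D1)
    if (any(reach)) expect_lte(mean(D2[reach]), mean(D1[reach]))
  }
})
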