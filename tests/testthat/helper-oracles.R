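# Independent brute-force oracles operating on dense adjacency matrices.
# Deliberately naive (loops, enumeration, matrix powers) so they share no
# code path with the package implementations.

rand_graph <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1L
    }
  }
  A
}

graph_from_adj <- function(A) {
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("i", "j"))
  structure(list(n_nodes = nrow(A), edges = idx), class = "netsign_graph")
}

adj_from_graph <- function(g) {
  A <- matrix(0L, g$n_nodes, g$n_nodes)
  if (nrow(g$edges) > 0) {
    for (e in seq_len(nrow(g$edges))) {
      A[g$edges[e, 1], g$edges[e, 2]] <- 1L
      A[g$edges[e, 2], g$edges[e, 1]] <- 1L
    }
  }
  A
}

# all-pairs shortest distances by Floyd-Warshall
bf_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A == 1L, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

bf_cpl_eff <- function(A) {
  D <- bf_distances(A)
  off <- D[row(D) != col(D)]
  fin <- is.finite(off)
  list(
    cpl = if (any(fin)) mean(off[fin]) else NaN,
    eff = mean(ifelse(fin, 1 / off, 0))
  )
}

bf_triangles_at <- function(A) {
  n <- nrow(A)
  t_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1L)
    cnt <- 0
    if (length(nb) >= 2) {
      for (a in seq_along(nb)) {
        for (b in seq_along(nb)) {
          if (a < b && A[nb[a], nb[b]] == 1L) cnt <- cnt + 1
        }
      }
    }
    t_i[i] <- cnt
  }
  t_i
}

bf_clustering <- function(A) {
  k <- rowSums(A)
  t_i <- bf_triangles_at(A)
  ifelse(k < 2, 0, 2 * t_i / (k * (k - 1)))
}

bf_transitivity <- function(A) {
  k <- rowSums(A)
  triads <- sum(k * (k - 1) / 2)
  if (triads == 0) return(0)
  sum(bf_triangles_at(A)) / triads # = 3 * triangles / triads
}

# betweenness by minimal-walk counting: the number of shortest s-t paths is
# (A^d)[s,t] with d = dist(s,t), and those through v factor as
# (A^d1)[s,v] (A^d2)[v,t] with d1 + d2 = d
bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  maxd <- max(D[is.finite(D)], 1)
  pow <- vector("list", maxd + 1)
  pow[[1]] <- diag(n) # A^0
  for (d in seq_len(maxd)) pow[[d + 1]] <- pow[[d]] %*% A
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      d <- D[s, t]
      if (!is.finite(d) || d == 0) next
      sigma <- pow[[d + 1]][s, t]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        d1 <- D[s, v]
        d2 <- D[v, t]
        if (is.finite(d1) && is.finite(d2) && d1 + d2 == d) {
          bc[v] <- bc[v] + pow[[d1 + 1]][s, v] * pow[[d2 + 1]][v, t] / sigma
        }
      }
    }
  }
  bc
}

bf_components <- function(A) {
  D <- bf_distances(A)
  memb <- integer(nrow(A))
  cid <- 0L
  for (i in seq_len(nrow(A))) {
    if (memb[i] == 0L) {
      cid <- cid + 1L
      memb[is.finite(D[i, ])] <- cid
    }
  }
  memb
}

bf_eigencent <- function(A, iters = 10000) {
  memb <- bf_components(A)
  sizes <- table(memb)
  big <- as.integer(names(sizes)[which.max(sizes)])
  idx <- which(memb == big)
  out <- numeric(nrow(A))
  if (length(idx) == 1) {
    out[idx] <- 1
    return(out)
  }
  B <- A[idx, idx]
  v <- rep(1, length(idx))
  for (it in seq_len(iters)) {
    # shift guarantees convergence on bipartite components
    v2 <- B %*% v + v
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < 1e-13) break
    v <- as.numeric(v2)
  }
  out[idx] <- v
  out
}

bf_local_eff <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1L)
    if (length(nb) >= 2) {
      out[i] <- bf_cpl_eff(A[nb, nb, drop = FALSE])$eff
    }
  }
  out
}

bf_participation <- function(A, memb) {
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    if (k == 0) next
    acc <- 0
    for (m in unique(memb)) {
      kis <- sum(A[i, memb == m])
      acc <- acc + (kis / k)^2
    }
    out[i] <- 1 - acc
  }
  out
}

bf_within_z <- function(A, memb) {
  n <- nrow(A)
  out <- numeric(n)
  for (m in unique(memb)) {
    idx <- which(memb == m)
    kin <- sapply(idx, function(i) sum(A[i, idx]))
    mu <- mean(kin)
    sdp <- sqrt(sum((kin - mu)^2) / length(kin))
    out[idx] <- if (sdp > 0) (kin - mu) / sdp else 0
  }
  out
}

bf_assortativity <- function(A) {
  k <- rowSums(A)
  xs <- c()
  ys <- c()
  for (i in seq_len(nrow(A) - 1)) {
    for (j in (i + 1):nrow(A)) {
      if (A[i, j] == 1L) {
        xs <- c(xs, k[i], k[j])
        ys <- c(ys, k[j], k[i])
      }
    }
  }
  if (length(xs) == 0 || stats::var(xs) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

# exhaustive pairwise AUC with ties counted half
bf_auc <- function(labels, probs) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (probs[i] > probs[j]) + 0.5 * (probs[i] == probs[j])
    }
  }
  total / (length(pos) * length(neg))
}

# modularity of a partition (for community-detection checks)
bf_modularity <- function(A, memb) {
  m2 <- sum(A) # 2m
  if (m2 == 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(A))) {
      if (memb[i] == memb[j]) q <- q + A[i, j] - k[i] * k[j] / m2
    }
  }
  q / m2
}
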