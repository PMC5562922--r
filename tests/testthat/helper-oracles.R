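# Fixture builders and independent brute-force oracles used across tests.
# Oracles deliberately avoid the code paths they check.

# wrap an adjacency matrix as a binary_network
net_from_adj <- function(A) {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  stopifnot(isSymmetric(unname(A)), all(diag(A) == 0))
  structure(
    list(adjacency = A, density = sum(A) / 2 / (nrow(A) * (nrow(A) - 1) / 2),
         density_requested = NA_real_, n_edges = sum(A) / 2),
    class = "binary_network"
  )
}

adj_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- 1L
    A[e[2], e[1]] <- 1L
  }
  A
}

complete_net <- function(n) net_from_adj(1 - diag(n))

path_net <- function(n) {
  net_from_adj(adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1))))
}

cycle_net <- function(n) {
  edges <- c(lapply(seq_len(n - 1), function(i) c(i, i + 1)), list(c(n, 1)))
  net_from_adj(adj_from_edges(n, edges))
}

star_net <- function(n) {
  net_from_adj(adj_from_edges(n, lapply(2:n, function(i) c(1, i))))
}

# two triangles sharing node 1: neighbors of the center form two disjoint edges
bowtie_net <- function() {
  net_from_adj(adj_from_edges(5, list(
    c(1, 2), c(1, 3), c(2, 3), c(1, 4), c(1, 5), c(4, 5)
  )))
}

random_net <- function(n, p_edge, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p_edge)
  net_from_adj(A + t(A))
}

random_connected_net <- function(n, p_edge, seed) {
  repeat {
    net <- random_net(n, p_edge, seed)
    if (all(is.finite(bf_distances(net$adjacency)))) return(net)
    seed <- seed + 1000
  }
}

# Floyd-Warshall all-pairs distances (independent of BFS/igraph paths)
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

bf_degree <- function(A) {
  vapply(seq_len(nrow(A)), function(i) sum(A[i, ] == 1), 0)
}

# clustering by explicit neighbor-pair enumeration
bf_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (A[nb[a], nb[b]] == 1) links <- links + 1
      }
    }
    2 * links / (k * (k - 1))
  }, 0)
}

# harmonic local efficiency by brute force over ordered neighbor pairs,
# with distances from Floyd-Warshall on the induced subgraph
bf_local_efficiency <- function(A, i) {
  nb <- which(A[i, ] == 1)
  k <- length(nb)
  if (k < 2) return(0)
  D <- bf_distances(A[nb, nb, drop = FALSE])
  tot <- 0
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a != b && is.finite(D[a, b])) tot <- tot + 1 / D[a, b]
    }
  }
  tot / (k * (k - 1))
}

# characteristic path length over reachable pairs from Floyd-Warshall
bf_cpl <- function(A) {
  D <- bf_distances(A)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

# Benjamini-Hochberg step-up written out literally
bf_bh_mask <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k_max <- 0
  for (k in seq_len(m)) {
    if (p[ord[k]] <= q * k / m) k_max <- k
  }
  mask <- rep(FALSE, m)
  if (k_max > 0) mask[ord[seq_len(k_max)]] <- TRUE
  mask
}

# exact two-tailed permutation p by exhaustive enumeration of assignments
bf_exact_perm_p <- function(a, b) {
  pooled <- c(a, b)
  obs <- mean(a) - mean(b)
  combs <- utils::combn(length(pooled), length(a))
  stats <- apply(combs, 2, function(idx) {
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  mean(abs(stats) >= abs(obs) - 1e-12)
}

# connectivity_matrix fixture from an explicit weight matrix
cm_from_weights <- function(W, p = NULL, n_samples = 100) {
  diag(W) <- 0
  if (is.null(p)) p <- matrix(0.5, nrow(W), ncol(W))
  diag(p) <- NA_real_
  structure(list(r = W, p = p, n_samples = n_samples),
            class = "connectivity_matrix")
}
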