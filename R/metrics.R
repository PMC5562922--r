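as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Nodal degree
#'
#' Number of edges incident to each node.
#'
#' @param net a `binary_network`.
#' @return Named integer vector, one entry per node.
#' @export
node_degree <- function(net) {
  d <- rowSums(net$adjacency)
  storage.mode(d) <- "integer"
  d
}

#' Nodal clustering coefficient
#'
#' For a node with degree `k >= 2`, the fraction of its neighbor pairs that
#' are themselves connected: `2 * t_i / (k * (k - 1))` where `t_i` is the
#' number of edges among the neighbors (equivalently, triangles through the
#' node).  Nodes with degree below 2 get 0.
#'
#' @param net a `binary_network`.
#' @return Numeric vector in `[0, 1]`, one entry per node.
#' @export
clustering_coefficient <- function(net) {
  A <- net$adjacency
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2     # triangles through each node
  cc <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  names(cc) <- rownames(A)
  cc
}

#' Global clustering coefficient and characteristic path length
#'
#' `C` is the mean of the nodal clustering coefficients over *all* nodes
#' (degree-deficient nodes contribute zeros).  `L` is the mean shortest-path
#' length over all unordered node pairs, from unweighted breadth-first
#' search.  If the network is disconnected, `L` is computed over reachable
#' pairs only, `connected` is `FALSE`, and a warning is emitted; the sweep
#' endpoints of the main pipeline are chosen so this does not occur there.
#'
#' @param net a `binary_network`.
#' @return List with `C`, `L`, `connected`.
#' @export
global_metrics <- function(net) {
  g <- as_igraph(net)
  C <- mean(clustering_coefficient(net))
  D <- igraph::distances(g)
  d <- D[upper.tri(D)]
  connected <- all(is.finite(d))
  if (!connected) {
    warning("network is disconnected; L computed over reachable pairs only")
    d <- d[is.finite(d)]
  }
  L <- if (length(d)) mean(d) else NA_real_
  list(C = C, L = L, connected = connected)
}

#' Characteristic path length
#'
#' Convenience wrapper returning only `L` and the connectedness flag from
#' [global_metrics()].
#'
#' @param net a `binary_network`.
#' @return List with `L` and `connected`.
#' @export
characteristic_path_length <- function(net) {
  gm <- global_metrics(net)
  list(L = gm$L, connected = gm$connected)
}

#' Nodal local efficiency
#'
#' Efficiency of information transfer among a node's immediate neighbors:
#' with `S` the neighbor set and `k = |S|`, the default (harmonic) form is
#' `E_loc = (1 / (k (k - 1))) * sum over ordered pairs (j, h) in S of
#' 1 / d_S(j, h)`, where `d_S` is the shortest-path distance inside the
#' subgraph induced by `S` (paths may not leave it) and `1 / Inf = 0` for
#' pairs disconnected within the subgraph.  Nodes with fewer than two
#' neighbors score 0.
#'
#' The harmonic form is well defined even when the neighbor subgraph is
#' disconnected, which happens routinely at the densities used here.  The
#' alternative reading "inverse of the average neighbor shortest path
#' length", `1 / mean(d_S)`, is available as `variant = "inverse_mean"` for
#' sensitivity analysis; it returns 0 whenever any neighbor pair is
#' unreachable within the subgraph.
#'
#' @param net a `binary_network`.
#' @param nodes nodes to evaluate (indices or names); default all.
#' @param variant `"harmonic"` (default) or `"inverse_mean"`.
#' @return Numeric vector in `[0, 1]`, one entry per requested node.
#' @export
local_efficiency <- function(net, nodes = NULL,
                             variant = c("harmonic", "inverse_mean")) {
  variant <- match.arg(variant)
  A <- net$adjacency
  n <- nrow(A)
  if (is.null(nodes)) {
    idx <- seq_len(n)
  } else if (is.character(nodes)) {
    idx <- match(nodes, rownames(A))
    if (anyNA(idx)) stop("unknown node(s): ",
                         paste(nodes[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(nodes)
    if (any(idx < 1 | idx > n)) stop("node index out of range")
  }
  # distances are computed inside the neighbor-induced subgraph only: local
  # efficiency gauges how the neighborhood reroutes around the node itself,
  # so paths through the rest of the graph do not count
  e <- vapply(idx, function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    d <- subgraph_distances(A[nb, nb, drop = FALSE])
    du <- d[upper.tri(d)]
    if (variant == "harmonic") {
      sum(2 / du[is.finite(du)]) / (k * (k - 1))
    } else {
      if (any(!is.finite(du))) 0 else 1 / mean(du)
    }
  }, 0)
  names(e) <- rownames(A)[idx]
  e
}

# All-pairs unweighted distances of a small dense adjacency matrix by
# repeated boolean matrix products (Inf where unreachable).
subgraph_distances <- function(S) {
  k <- nrow(S)
  D <- matrix(Inf, k, k)
  diag(D) <- 0
  D[S == 1] <- 1
  reach <- S
  step <- 1
  while (step < k && any(!is.finite(D))) {
    reach <- (reach %*% S > 0) * 1
    step <- step + 1
    newly <- reach == 1 & !is.finite(D)
    diag(newly) <- FALSE
    if (!any(newly)) break
    D[newly] <- step
  }
  D
}

#' All nodal metrics of one network
#'
#' @param net a `binary_network`.
#' @param le_variant local-efficiency variant, see [local_efficiency()].
#' @return List with `degree`, `clustering`, `local_efficiency` vectors.
#' @export
nodal_metrics <- function(net, le_variant = "harmonic") {
  list(
    degree = node_degree(net),
    clustering = clustering_coefficient(net),
    local_efficiency = local_efficiency(net, variant = le_variant)
  )
}
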