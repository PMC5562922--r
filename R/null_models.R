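#' Degree-preserving rewiring (matched random network)
#'
#' Randomizes a network by repeated double-edge swaps: two edges (a,b) and
#' (c,d) are replaced by (a,d) and (c,b) whenever neither new edge exists
#' and no self-loop arises.  Every node's degree is preserved exactly, so
#' the rewired graph is a degree-matched null for the input.  The default
#' budget of `10 * |E|` attempted swaps is a standard mixing heuristic.
#'
#' @param net a `binary_network`.
#' @param n_swaps attempted swaps (default `10 * n_edges`).
#' @param seed optional RNG seed.
#' @return A rewired `binary_network` with identical degree sequence.
#' @export
rewire_degree_preserving <- function(net, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(net, "binary_network"), net$n_edges >= 2)
  n_swaps <- n_swaps %||% (10 * net$n_edges)
  with_seed(seed, {
    g <- as_igraph(net)
    g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                   niter = n_swaps))
    A <- igraph::as_adjacency_matrix(g2, sparse = FALSE)
    storage.mode(A) <- "integer"
    dimnames(A) <- dimnames(net$adjacency)
    structure(
      list(adjacency = A, density = net$density,
           density_requested = net$density_requested, n_edges = net$n_edges),
      class = "binary_network"
    )
  })
}

#' Normalized global metrics against a matched-random ensemble
#'
#' Divides the network's global clustering coefficient `C` and
#' characteristic path length `L` by their means over `ensemble_size`
#' degree-matched random networks generated by
#' [rewire_degree_preserving()] (or, with `null = "gnm"`, Erdos-Renyi
#' G(n, m) graphs matching only node and edge counts).  Values of
#' `C_nor > 1` with `L_nor` near 1 indicate small-world organization.
#'
#' Connectivity is not enforced on ensemble members -- enforcement would
#' bias the null; members that come out disconnected contribute their
#' reachable-pair `L` and are tallied in `n_disconnected`.
#'
#' @param net a `binary_network` (a warning is issued if disconnected).
#' @param ensemble_size number of random networks (field convention: 1000).
#' @param seed optional RNG seed for the ensemble.
#' @param null `"rewire"` (degree-matched, default) or `"gnm"` (size-matched).
#' @param keep_ensemble if `TRUE`, retain per-graph `C` and `L`.
#' @return List with `C_nor`, `L_nor`, `C`, `L`, `mean_C_rand`,
#'   `mean_L_rand`, `n_disconnected`, `ensemble_size`, and optionally
#'   `ensemble` (data.frame of per-graph C and L).
#' @export
normalized_global_metrics <- function(net, ensemble_size = 1000, seed = NULL,
                                      null = c("rewire", "gnm"),
                                      keep_ensemble = FALSE) {
  null <- match.arg(null)
  stopifnot(ensemble_size >= 1)
  obs <- global_metrics(net)
  if (!obs$connected) warning("observed network is disconnected")
  n <- nrow(net$adjacency)
  with_seed(seed, {
    Cs <- numeric(ensemble_size)
    Ls <- numeric(ensemble_size)
    disc <- 0L
    for (b in seq_len(ensemble_size)) {
      rnet <- if (null == "rewire") {
        rewire_degree_preserving(net)
      } else {
        g <- igraph::sample_gnm(n, net$n_edges)
        A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
        storage.mode(A) <- "integer"
        structure(list(adjacency = A, density = net$density,
                       density_requested = net$density_requested,
                       n_edges = net$n_edges),
                  class = "binary_network")
      }
      gm <- withCallingHandlers(
        global_metrics(rnet),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (!gm$connected) disc <- disc + 1L
      Cs[b] <- gm$C
      Ls[b] <- gm$L
    }
    mC <- mean(Cs)
    mL <- mean(Ls)
    if (mC == 0) stop("degenerate degree sequence: random ensemble has mean C = 0")
    out <- list(
      C_nor = obs$C / mC, L_nor = obs$L / mL,
      C = obs$C, L = obs$L,
      mean_C_rand = mC, mean_L_rand = mL,
      n_disconnected = disc, ensemble_size = ensemble_size
    )
    if (keep_ensemble) out$ensemble <- data.frame(C = Cs, L = Ls)
    out
  })
}
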