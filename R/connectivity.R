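#' Pearson connectivity matrix of one subject
#'
#' Pairwise Pearson correlation between all region time courses, with
#' two-sided p-values from the exact t transform
#' `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.  The
#' diagonal of `r` is set to zero (self-correlations carry no connectivity
#' information).
#'
#' @param record a `subject_record`, or a regions x timepoints matrix.
#' @return A `connectivity_matrix`: list with `r`, `p` (both n x n,
#'   symmetric), and `n_samples`.
#' @export
pearson_connectivity <- function(record) {
  ts <- if (inherits(record, "subject_record")) record$timeseries else record
  stopifnot(is.matrix(ts))
  n_t <- ncol(ts)
  if (n_t < 3) stop("need at least 3 timepoints to correlate")
  v <- apply(ts, 1, stats::var)
  if (any(v == 0)) {
    bad <- rownames(ts)[v == 0] %||% as.character(which(v == 0))
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(ts))
  r[r > 1] <- 1
  r[r < -1] <- -1
  tstat <- r * sqrt((n_t - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n_t - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(r) <- 0
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n_samples = n_t), class = "connectivity_matrix")
}

#' Density sweep grid
#'
#' The ordered set of connection densities at which networks are built.
#' The default grid, 24.5% to 30% in steps of 0.5%, spans the range in
#' which whole-brain correlation networks are typically fully connected at
#' the low end while every retained edge remains FDR-significant at the
#' high end (see [find_min_connected_density()] and
#' [find_max_density_fdr()], which derive these endpoints from data).
#'
#' @param d_min,d_max sweep endpoints as fractions of all node pairs.
#' @param step grid interval.
#' @return A `density_sweep`: list with `d_min`, `d_max`, `step`, and the
#'   inclusive `densities` grid.
#' @export
#' @examples
#' length(density_sweep()$densities) # 12
density_sweep <- function(d_min = 0.245, d_max = 0.300, step = 0.005) {
  stopifnot(d_min > 0, d_max < 1, d_min <= d_max, step > 0)
  k <- round((d_max - d_min) / step)
  densities <- round(d_min + step * (0:k), 10)
  structure(list(d_min = d_min, d_max = d_max, step = step,
                 densities = densities),
            class = "density_sweep")
}

#' Threshold a connectivity matrix at a connection density
#'
#' Retains the `round(density * n(n-1)/2)` edges with the largest
#' correlations (round half away from zero).  Ranking is by signed `r` by
#' default -- after global-signal regression, negative correlations exist
#' and the convention in this literature is to keep the strongest positive
#' connections; set `rank = "absolute"` to rank by `|r|`.  Ties at the
#' cutoff are broken by ascending (row, column) order so thresholding is
#' deterministic.
#'
#' @param cm a `connectivity_matrix`.
#' @param density target fraction of present edges, in (0, 1).
#' @param rank `"signed"` (default) or `"absolute"` edge ranking.
#' @return A `binary_network`: list with `adjacency` (0/1 symmetric, zero
#'   diagonal), `density` (realized), `density_requested`, `n_edges`.
#' @export
threshold_by_density <- function(cm, density, rank = c("signed", "absolute")) {
  rank <- match.arg(rank)
  stopifnot(inherits(cm, "connectivity_matrix"), density > 0, density < 1)
  n <- nrow(cm$r)
  m <- round_half_up(density * n_pairs(n))
  if (m < 1) stop("density ", density, " yields an empty edge set")
  pairs <- upper_pairs(n)
  w <- cm$r[pairs]
  if (rank == "absolute") w <- abs(w)
  # order(-w) is a stable sort, so equal weights fall back to the ascending
  # lexicographic pair order of `pairs`
  keep <- order(-w)[seq_len(m)]
  A <- matrix(0L, n, n, dimnames = dimnames(cm$r))
  A[pairs[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  structure(
    list(adjacency = A, density = m / n_pairs(n),
         density_requested = density, n_edges = m),
    class = "binary_network"
  )
}

#' Networks across a density sweep
#'
#' One binary network per grid density.  Because every network keeps the
#' top-`k` edges under the same ranking, edge sets are nested: the network
#' at a lower density is a subgraph of the network at any higher density.
#'
#' @inheritParams threshold_by_density
#' @param sweep a [density_sweep()].
#' @return List of `binary_network`, one per density, in grid order.
#' @export
build_sweep_networks <- function(cm, sweep = density_sweep(),
                                 rank = c("signed", "absolute")) {
  rank <- match.arg(rank)
  lapply(sweep$densities, function(d) threshold_by_density(cm, d, rank))
}

#' Minimum density at which every subject's network is connected
#'
#' Scans the density grid upward from one edge-budget step above zero and
#' returns the first density at which the thresholded network of every
#' subject forms a single connected component.  This is the data-driven
#' rule for the sweep's lower endpoint: below it, some subject has an
#' isolated region and characteristic path length is ill-defined.
#'
#' @param cohort_cms list of `connectivity_matrix`, one per subject.
#' @param step grid interval scanned (default 0.005).
#' @param rank edge ranking passed to [threshold_by_density()].
#' @return The smallest grid density with all subjects connected.
#' @export
find_min_connected_density <- function(cohort_cms, step = 0.005,
                                       rank = c("signed", "absolute")) {
  rank <- match.arg(rank)
  stopifnot(length(cohort_cms) >= 1)
  # Adding edges can only merge components, so connectivity is monotone in
  # the edge count: find each subject's minimal connected edge budget by
  # binary search, then the first grid density whose budget covers them all.
  k_conn <- vapply(cohort_cms, function(cm) {
    n <- nrow(cm$r)
    np <- n_pairs(n)
    pairs <- upper_pairs(n)
    w <- cm$r[pairs]
    if (rank == "absolute") w <- abs(w)
    ord <- order(-w)
    connected_at <- function(k) {
      A <- matrix(0L, n, n)
      A[pairs[ord[seq_len(k)], , drop = FALSE]] <- 1L
      is_connected_adj(A + t(A))
    }
    if (!connected_at(np)) return(NA_real_)
    lo <- n - 1       # a connected graph needs at least n - 1 edges
    hi <- np
    while (lo < hi) {
      mid <- (lo + hi) %/% 2
      if (connected_at(mid)) hi <- mid else lo <- mid + 1
    }
    lo
  }, 0)
  if (anyNA(k_conn)) {
    stop("no density below 1 yields a connected network for every subject")
  }
  nps <- vapply(cohort_cms, function(cm) n_pairs(nrow(cm$r)), 0)
  for (k in seq_len(floor(1 / step))) {
    d <- round(k * step, 10)
    if (d >= 1) break
    if (all(round_half_up(d * nps) >= k_conn)) return(d)
  }
  stop("no grid density below 1 covers the connected edge budget")
}

is_connected_adj <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::is_connected(g)
}

#' Maximum density at which all retained edges are FDR-significant
#'
#' For each subject, Benjamini-Hochberg at level `q` is applied to the
#' `n(n-1)/2` unique off-diagonal correlation p-values, and the fraction of
#' node pairs declared significant is recorded.  The minimum of these
#' fractions across subjects is returned: at any density at or below it,
#' every retained edge is FDR-significant for every subject.  This is the
#' data-driven rule for the sweep's upper endpoint; above it the weakest
#' retained correlations are statistically indistinguishable from zero for
#' at least one subject, and the network degrades toward a random graph.
#'
#' @param cohort_cms list of `connectivity_matrix`.
#' @param q FDR level (default 0.05).
#' @return The cohort-wide maximum density as a fraction.
#' @export
find_max_density_fdr <- function(cohort_cms, q = 0.05) {
  stopifnot(length(cohort_cms) >= 1, q > 0, q < 1)
  fracs <- vapply(cohort_cms, function(cm) {
    p <- cm$p[upper.tri(cm$p)]
    if (length(p) == 0 || anyNA(p)) stop("connectivity p-values missing")
    mean(stats::p.adjust(p, method = "BH") <= q)
  }, 0)
  min(fracs)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("Connectivity matrix: %d regions, %d timepoints\n",
              nrow(x$r), x$n_samples))
  invisible(x)
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("Binary network: %d nodes, %d edges (density %.4f)\n",
              nrow(x$adjacency), x$n_edges, x$density))
  invisible(x)
}
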