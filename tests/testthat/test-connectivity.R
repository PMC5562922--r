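test_that("pearson connectivity matches direct formula evaluation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  ts <- rbind(a = x, b = y)
  cm <- pearson_connectivity(ts)
  # hand covariance oracle
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm$r[1, 2], r_hand)
  t_hand <- r_hand * sqrt((5 - 2) / (1 - r_hand^2))
  expect_equal(cm$p[1, 2], 2 * stats::pt(-abs(t_hand), df = 3))
  expect_equal(diag(cm$r), c(a = 0, b = 0))
  expect_equal(cm$n_samples, 5)
})

test_that("perfectly dependent regions give r of +/- 1", {
  base <- c(0.3, -1.2, 0.5, 2.0, -0.7, 1.1)
  ts <- rbind(a = base, b = base, c = -base)
  cm <- pearson_connectivity(ts)
  expect_equal(cm$r[1, 2], 1)
  expect_equal(cm$r[1, 3], -1)
  expect_true(isSymmetric(cm$r))
})

test_that("degenerate inputs are rejected by name", {
  ts <- rbind(R1 = c(1, 2, 3, 4), R2 = c(5, 5, 5, 5))
  expect_error(pearson_connectivity(ts), "R2")
  expect_error(pearson_connectivity(rbind(a = 1:2, b = 2:1)), "timepoints")
})

test_that("the default density sweep has 12 grid points", {
  sw <- density_sweep()
  expect_equal(length(sw$densities), 12)
  expect_equal(sw$densities[1], 0.245)
  expect_equal(sw$densities[12], 0.300)
  expect_equal(diff(sw$densities), rep(0.005, 11), tolerance = 1e-9)
})

test_that("thresholding keeps exactly the strongest edges", {
  # 4-node matrix with distinct r values, density 0.5 -> 3 largest-r pairs
  W <- matrix(0, 4, 4)
  vals <- c(0.9, 0.1, 0.7, 0.3, 0.8, 0.5)
  W[upper.tri(W)] <- vals
  W <- W + t(W)
  cm <- cm_from_weights(W)
  net <- threshold_by_density(cm, 0.5)
  expect_equal(net$n_edges, 3)
  # exhaustive sort oracle: top-3 weights
  pairs <- which(upper.tri(W), arr.ind = TRUE)
  top <- pairs[order(-W[upper.tri(W)])[1:3], , drop = FALSE]
  expect_true(all(net$adjacency[top] == 1))
  expect_equal(sum(net$adjacency) / 2, 3)
  # signed ranking: strong negative correlations are weak edges
  W2 <- W
  W2[1, 2] <- W2[2, 1] <- -0.95
  net2 <- threshold_by_density(cm_from_weights(W2), 0.5)
  expect_equal(net2$adjacency[1, 2], 0L)
  net2a <- threshold_by_density(cm_from_weights(W2), 0.5, rank = "absolute")
  expect_equal(net2a$adjacency[1, 2], 1L)
})

test_that("edge budgets follow round-half-away-from-zero of density x pairs", {
  set.seed(42)
  W <- matrix(0, 90, 90)
  W[upper.tri(W)] <- stats::runif(90 * 89 / 2, -1, 1)
  W <- W + t(W)
  cm <- cm_from_weights(W)
  expect_equal(threshold_by_density(cm, 0.245)$n_edges, 981)
  expect_equal(threshold_by_density(cm, 0.300)$n_edges, 1202)
  sw <- density_sweep()
  budgets <- vapply(build_sweep_networks(cm, sw), `[[`, 0, "n_edges")
  expect_equal(budgets, round(sw$densities * 4005 + 1e-9))
  expect_true(all(diff(budgets) >= 0))
})

test_that("sweep networks are nested and permutation-equivariant", {
  set.seed(7)
  n <- 20
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- stats::runif(n * (n - 1) / 2, -1, 1)
  W <- W + t(W)
  cm <- cm_from_weights(W)
  nets <- build_sweep_networks(cm, density_sweep())
  for (i in seq_len(length(nets) - 1)) {
    expect_true(all(nets[[i]]$adjacency <= nets[[i + 1]]$adjacency),
                info = sprintf("densities %d vs %d", i, i + 1))
  }
  # relabeling regions permutes the adjacency identically
  perm <- sample(n)
  cmp <- cm_from_weights(W[perm, perm])
  for (d in c(0.245, 0.3)) {
    A <- threshold_by_density(cm, d)$adjacency
    Ap <- threshold_by_density(cmp, d)$adjacency
    expect_equal(unname(Ap), unname(A[perm, perm]), info = paste("density", d))
  }
})

test_that("minimum connected density matches an upward grid scan", {
  # ring of strong edges plus weak fill: connected once the ring's spanning
  # path is complete
  n <- 10
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- seq(0.01, 0.2, length.out = n * (n - 1) / 2)
  W <- W + t(W)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    W[i, j] <- W[j, i] <- 0.9 + i / 100
  }
  cm <- cm_from_weights(W)
  got <- find_min_connected_density(list(cm), step = 0.005)
  # oracle: scan the grid directly
  scan <- NA
  for (k in 1:199) {
    d <- k * 0.005
    if (round(d * 45 + 1e-9) < 1) next
    g <- igraph::graph_from_adjacency_matrix(
      threshold_by_density(cm, d)$adjacency, mode = "undirected")
    if (igraph::is_connected(g)) { scan <- d; break }
  }
  expect_equal(got, scan)

  # star-dominant weights: the 5 hub edges rank first, so the graph is
  # connected exactly once all 5 are in; first grid budget >= 5 is at 0.300
  Ws <- matrix(0, 6, 6)
  Ws[upper.tri(Ws)] <- seq(0.01, 0.1, length.out = 15)
  Ws[1, 2:6] <- seq(0.9, 0.5, length.out = 5)
  Ws[lower.tri(Ws)] <- t(Ws)[lower.tri(Ws)]
  cms <- cm_from_weights(Ws)
  expect_equal(find_min_connected_density(list(cms), step = 0.005), 0.300)

  # adding a more fragmented subject can only raise the result
  expect_gte(find_min_connected_density(list(cm, cms), step = 0.005),
             find_min_connected_density(list(cm), step = 0.005))
})

test_that("FDR max-density rule reproduces the step-up fraction", {
  # 10 unique pairs with hand-checkable BH outcome: 5/10 significant
  p_up <- c(0.001, 0.002, 0.003, 0.004, 0.005, 0.2, 0.3, 0.4, 0.5, 0.6)
  P <- matrix(NA_real_, 5, 5)
  P[upper.tri(P)] <- p_up
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  cm <- cm_from_weights(matrix(0.5, 5, 5), p = P)
  expect_equal(find_max_density_fdr(list(cm), q = 0.05), 0.5)
  expect_equal(mean(bf_bh_mask(p_up, 0.05)), 0.5)

  all0 <- cm_from_weights(matrix(0.9, 4, 4), p = matrix(0, 4, 4))
  expect_equal(find_max_density_fdr(list(all0), q = 0.05), 1.0)
  all1 <- cm_from_weights(matrix(0.1, 4, 4), p = matrix(1, 4, 4))
  expect_equal(find_max_density_fdr(list(all1), q = 0.05), 0.0)

  # minimum across subjects, monotone nonincreasing in stricter q
  expect_equal(find_max_density_fdr(list(cm, all1), q = 0.05), 0.0)
  expect_lte(find_max_density_fdr(list(cm), q = 0.01),
             find_max_density_fdr(list(cm), q = 0.05))
})
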