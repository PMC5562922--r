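#' Area under a metric-versus-density curve
#'
#' Trapezoidal integral of metric values over the density grid:
#' `sum (v_i + v_{i+1})/2 * (d_{i+1} - d_i)`.  Summarizing the threshold
#' sweep by its AUC removes the arbitrariness of any single density and is
#' the quantity compared between groups.
#'
#' @param values metric values, one per density.
#' @param densities strictly increasing density grid of the same length.
#' @return The scalar AUC.
#' @export
#' @examples
#' curve_auc(rep(1, 12), density_sweep()$densities) # 0.055
curve_auc <- function(values, densities) {
  if (length(values) != length(densities)) {
    stop("values and densities differ in length")
  }
  if (length(values) < 2) stop("need at least 2 points")
  if (any(diff(densities) <= 0)) stop("densities must be strictly increasing")
  dd <- diff(densities)
  sum((values[-length(values)] + values[-1]) / 2 * dd)
}

#' Permutation test for a group difference in means
#'
#' The observed statistic is `mean(values_a) - mean(values_b)`.  Each of the
#' `n_perm` repetitions reassigns the pooled subjects at random into two
#' groups of the original sizes and recomputes the statistic, forming the
#' permutation null.  The two-tailed p-value is the percentile position of
#' the observed statistic in that null, with the add-one estimator
#' `p = (1 + #{|null| >= |obs|}) / (1 + n_perm)` so p is never exactly 0.
#'
#' @param values_a,values_b numeric vectors for the two groups.
#' @param n_perm number of permutations (field convention: 10000).
#' @param seed optional RNG seed.
#' @param keep_null if `TRUE`, return the null distribution.
#' @return List with `observed_diff`, `p_two_tailed`, `n_perm`, and
#'   optionally `null_distribution`.
#' @export
permutation_group_test <- function(values_a, values_b, n_perm = 10000,
                                   seed = NULL, keep_null = FALSE) {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1, n_perm >= 100)
  pooled <- c(values_a, values_b)
  n_a <- length(values_a)
  obs <- mean(values_a) - mean(values_b)
  if (stats::var(pooled) == 0) {
    warning("all values identical; permutation test degenerate")
    return(list(observed_diff = 0, p_two_tailed = 1, n_perm = n_perm))
  }
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), n_a)
      mean(pooled[idx]) - mean(pooled[-idx])
    }, 0)
  })
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
  out <- list(observed_diff = obs, p_two_tailed = p, n_perm = n_perm)
  if (keep_null) out$null_distribution <- null
  out
}

# Vectorized permutation test over the columns of a subjects x nodes AUC
# matrix, using one shared set of subject permutations across nodes (the
# standard choice when the node-wise p-values feed a joint FDR correction).
# Returns observed differences and add-one two-tailed p per column.
permutation_group_test_matrix <- function(auc_a, auc_b, n_perm = 10000,
                                          seed = NULL) {
  stopifnot(is.matrix(auc_a), is.matrix(auc_b), ncol(auc_a) == ncol(auc_b))
  pooled <- rbind(auc_a, auc_b)
  n_a <- nrow(auc_a)
  n <- nrow(pooled)
  obs <- colMeans(auc_a) - colMeans(auc_b)
  with_seed(seed, {
    exceed <- integer(ncol(pooled))
    for (i in seq_len(n_perm)) {
      sel <- sample.int(n, n_a)
      d <- colMeans(pooled[sel, , drop = FALSE]) -
        colMeans(pooled[-sel, , drop = FALSE])
      exceed <- exceed + (abs(d) >= abs(obs))
    }
    list(observed_diff = obs,
         p_two_tailed = (1 + exceed) / (1 + n_perm),
         n_perm = n_perm)
  })
}

#' Benjamini-Hochberg significance mask
#'
#' Step-up false-discovery-rate control at level `q` over a family of
#' p-values (here typically the 90 nodes of one nodal metric).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical vector: `TRUE` where the hypothesis is rejected.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Pearson correlation between a nodal metric and behavior
#'
#' Sample Pearson r with the two-sided t-based p-value, as used to relate
#' per-subject nodal AUCs to behavioral scores within each group
#' separately.
#'
#' @param nodal_auc per-subject metric values.
#' @param scores per-subject behavioral scores, same order.
#' @return List with `r`, `p`, `n`.
#' @export
behavior_correlation <- function(nodal_auc, scores) {
  stopifnot(length(nodal_auc) == length(scores))
  if (length(nodal_auc) < 4) stop("need at least 4 paired observations")
  if (stats::var(nodal_auc) == 0 || stats::var(scores) == 0) {
    stop("zero variance in metric or scores")
  }
  ct <- stats::cor.test(nodal_auc, scores, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(scores))
}

#' Pooled two-sample t-test from summary statistics
#'
#' Recomputes an independent-samples t statistic (pooled variance,
#' `df = n_a + n_b - 2`) from printed group means, SDs and sizes -- e.g. to
#' verify reported behavioral comparisons when raw scores are unavailable.
#'
#' @param mean_a,sd_a,n_a summary statistics of group A.
#' @param mean_b,sd_b,n_b summary statistics of group B.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' two_sample_t_from_summary(56.97, 8.01, 72, 48.16, 8.30, 72)$t # ~6.48
two_sample_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(sd_a > 0, sd_b > 0, n_a >= 2, n_b >= 2)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
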