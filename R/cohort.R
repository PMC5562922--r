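#' Specify a synthetic two-group cohort
#'
#' A cohort spec describes a population of region-of-interest (ROI) time
#' series with block-modular correlation structure, a planted within-module
#' connectivity increase in one ("trained") group, and behavioral scores
#' whose group means and SDs are set explicitly and which covary with the
#' realized planted-module connectivity in the trained group only.
#'
#' Each subject's time series is drawn as `n_timepoints` i.i.d. multivariate
#' normal vectors with unit variances and the group's population correlation
#' matrix: `rho_within` for same-module region pairs, `rho_between` for
#' cross-module pairs, and `rho_within + delta` for pairs inside the planted
#' module when the subject is in the trained group.  Temporal autocorrelation
#' is deliberately absent so that the t-distribution p-values attached to
#' sample correlations downstream are exact.
#'
#' Behavioral defaults follow a two-group arithmetic-training design:
#' trained mean 56.97, SD 8.01; control mean 48.16, SD 8.30 (composite
#' math-test t-score units), with 72 subjects per group and 175 retained
#' timepoints per subject.
#'
#' @param n_regions number of ROIs (network nodes).
#' @param n_timepoints timepoints per subject.
#' @param n_per_group subjects per group.
#' @param module_assignment integer vector of length `n_regions` mapping each
#'   region to a module id.  Default: a planted module of `planted_size`
#'   regions followed by contiguous modules of roughly 15 regions.
#' @param rho_within population correlation for same-module pairs.
#' @param rho_between population correlation for cross-module pairs; must be
#'   strictly less than `rho_within`.
#' @param planted_module module id that receives the group effect.
#' @param planted_size size of the default planted module (ignored when
#'   `module_assignment` is supplied).
#' @param delta correlation increment added to planted-module within-pairs
#'   for the trained group; `rho_within + delta` must stay below 1.
#' @param behavior_mean_by_group,behavior_sd_by_group named numeric vectors
#'   with elements `trained` and `control` (score units).
#' @param behavior_coupling slope (score units per SD of realized
#'   planted-module connectivity) linking a trained subject's realized
#'   within-planted-module mean correlation to its score.  Must be smaller in
#'   magnitude than the trained group's score SD so the marginal SD can be
#'   preserved.
#' @param noise_sd optional residual score noise SD.  Default `NULL` derives
#'   it as `sqrt(sd^2 - coupling^2)` in the trained group (and `sd` in the
#'   control group) so the marginal score SD matches `behavior_sd_by_group`.
#' @param seed RNG seed for cohort generation.
#'
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_regions = 30, n_per_group = 10, seed = 1)
#' cohort <- generate_cohort(spec)
cohort_spec <- function(n_regions = 90,
                        n_timepoints = 175,
                        n_per_group = 72,
                        module_assignment = NULL,
                        rho_within = 0.22,
                        rho_between = 0.12,
                        planted_module = 1L,
                        planted_size = 8L,
                        delta = 0.05,
                        behavior_mean_by_group = c(trained = 56.97, control = 48.16),
                        behavior_sd_by_group = c(trained = 8.01, control = 8.30),
                        behavior_coupling = 7.5,
                        noise_sd = NULL,
                        seed = 1L) {
  if (is.null(module_assignment)) {
    module_assignment <- default_modules(n_regions, planted_size)
  }
  stopifnot(length(module_assignment) == n_regions)
  if (!(rho_between >= 0 && rho_between < rho_within && rho_within < 1)) {
    stop("require 0 <= rho_between < rho_within < 1")
  }
  if (rho_within + delta >= 1) stop("rho_within + delta must be < 1")
  if (!planted_module %in% module_assignment) {
    stop("planted_module not present in module_assignment")
  }
  for (g in c("trained", "control")) {
    if (is.na(behavior_mean_by_group[g]) || is.na(behavior_sd_by_group[g])) {
      stop("behavior means/SDs must be named for 'trained' and 'control'")
    }
  }
  if (abs(behavior_coupling) >= behavior_sd_by_group["trained"]) {
    stop("behavior_coupling magnitude must be below the trained-group score SD")
  }
  spec <- structure(
    list(
      n_regions = as.integer(n_regions),
      n_timepoints = as.integer(n_timepoints),
      n_per_group = as.integer(n_per_group),
      module_assignment = as.integer(module_assignment),
      rho_within = rho_within,
      rho_between = rho_between,
      planted_module = as.integer(planted_module),
      delta = delta,
      behavior_mean_by_group = behavior_mean_by_group,
      behavior_sd_by_group = behavior_sd_by_group,
      behavior_coupling = behavior_coupling,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  # validate positive definiteness of both group matrices up front
  for (g in c("trained", "control")) build_population_correlation(spec, g)
  spec
}

# Default partition: planted module first, remaining regions in contiguous
# modules of ~15 (the scale of anatomical lobar groupings).
default_modules <- function(n_regions, planted_size = 8L, other_size = 15L) {
  if (planted_size > n_regions) stop("planted module larger than network")
  rest <- n_regions - planted_size
  if (rest == 0) return(rep(1L, n_regions))
  n_other <- max(1L, round(rest / other_size))
  sizes <- rep(rest %/% n_other, n_other)
  if (rest %% n_other > 0) sizes[seq_len(rest %% n_other)] <- sizes[seq_len(rest %% n_other)] + 1L
  rep(seq_len(n_other + 1L), times = c(planted_size, sizes))
}

#' Population correlation matrix for one group
#'
#' Realizes the block structure of a [cohort_spec()]: unit diagonal,
#' `rho_within` inside modules, `rho_between` across modules, and
#' `rho_within + delta` inside the planted module for the trained group.
#' The matrix is checked for positive definiteness by Cholesky
#' factorization; an invalid parameter combination is rejected with the
#' smallest eigenvalue reported.
#'
#' @param spec a [cohort_spec()].
#' @param group `"trained"` or `"control"`.
#' @return The `n_regions` x `n_regions` correlation matrix.
#' @export
build_population_correlation <- function(spec, group = c("trained", "control")) {
  group <- match.arg(group)
  mod <- spec$module_assignment
  same <- outer(mod, mod, "==")
  R <- ifelse(same, spec$rho_within, spec$rho_between)
  if (group == "trained" && spec$delta != 0) {
    planted <- mod == spec$planted_module
    block <- outer(planted, planted, "&")
    R[block] <- spec$rho_within + spec$delta
  }
  diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf(
      "population correlation matrix for group '%s' is not positive definite (min eigenvalue %.3g)",
      group, ev
    ))
  }
  attr(R, "chol") <- ch
  R
}

# Mean sample correlation over the unordered within-pairs of the planted
# module -- the "realized planted-module connectivity" that behavior scores
# couple to.
realized_planted_connectivity <- function(ts, spec) {
  planted <- which(spec$module_assignment == spec$planted_module)
  if (length(planted) < 2) return(NA_real_)
  r <- stats::cor(t(ts[planted, , drop = FALSE]))
  mean(r[upper.tri(r)])
}

#' Draw one synthetic subject
#'
#' Samples `n_timepoints` independent multivariate-normal vectors with the
#' group's population correlation and attaches a behavioral score.  The
#' score couples to the subject's *realized* (sample) planted-module
#' connectivity in the trained group: standardizing that quantity requires a
#' cohort-level mean and SD, so when `behavior_coupling != 0` a
#' `standardizer` must be supplied (as [generate_cohort()] does internally
#' after drawing the whole group).
#'
#' @param spec a [cohort_spec()].
#' @param group `"trained"` or `"control"`.
#' @param subject_id subject identifier string.
#' @param seed optional RNG seed for this draw (bit-reproducible records).
#' @param standardizer optional `list(mean =, sd =)` used to z-score the
#'   realized planted-module connectivity before applying the coupling.
#' @return A `subject_record`: list with `subject_id`, `group`, `timeseries`
#'   (regions x timepoints matrix), `behavior_score`, and the realized
#'   planted-module connectivity as `planted_connectivity`.
#' @export
sample_subject <- function(spec, group = c("trained", "control"),
                           subject_id = "s1", seed = NULL,
                           standardizer = NULL) {
  group <- match.arg(group)
  R <- build_population_correlation(spec, group)
  with_seed(seed, {
    rec <- draw_subject(spec, group, subject_id, attr(R, "chol"))
    rec$behavior_score <- score_subject(
      spec, group, rec$planted_connectivity, rec$score_noise_z, standardizer
    )
    rec$score_noise_z <- NULL
    rec
  })
}

# timeseries + realized connectivity + a reserved N(0,1) noise draw for the
# score (scored later, once the cohort-level standardizer is known)
draw_subject <- function(spec, group, subject_id, chol_R) {
  z <- matrix(stats::rnorm(spec$n_timepoints * spec$n_regions),
              nrow = spec$n_timepoints)
  ts <- t(z %*% chol_R)             # regions x timepoints
  dimnames(ts) <- list(sprintf("R%03d", seq_len(spec$n_regions)),
                       sprintf("t%d", seq_len(spec$n_timepoints)))
  structure(
    list(
      subject_id = subject_id,
      group = group,
      timeseries = ts,
      behavior_score = NA_real_,
      planted_connectivity = realized_planted_connectivity(ts, spec),
      score_noise_z = stats::rnorm(1)
    ),
    class = "subject_record"
  )
}

score_subject <- function(spec, group, planted_conn, noise_z, standardizer) {
  mu <- spec$behavior_mean_by_group[[group]]
  sigma <- spec$behavior_sd_by_group[[group]]
  coupling <- if (group == "trained") spec$behavior_coupling else 0
  if (coupling != 0) {
    if (is.null(standardizer)) {
      stop("behavior_coupling != 0 needs a cohort-level standardizer; ",
           "use generate_cohort() or pass `standardizer = list(mean=, sd=)`")
    }
    z <- (planted_conn - standardizer$mean) / standardizer$sd
  } else {
    z <- 0
  }
  resid_sd <- spec$noise_sd %||% sqrt(max(sigma^2 - coupling^2, 0))
  mu + coupling * z + resid_sd * noise_z
}

#' Generate a full two-group cohort
#'
#' Draws `n_per_group` subjects per group under the spec's seed.  Trained
#' subjects' scores couple to their realized planted-module connectivity,
#' z-scored across the trained group, so the in-sample score/connectivity
#' correlation is `behavior_coupling / behavior_sd` up to residual noise.
#'
#' @param spec a [cohort_spec()].
#' @return A `cohort`: list with `subjects` (list of `subject_record`),
#'   `manifest` (data.frame: subject_id, group, behavior_score), and the
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  chols <- list(
    trained = attr(build_population_correlation(spec, "trained"), "chol"),
    control = attr(build_population_correlation(spec, "control"), "chol")
  )
  subjects <- with_seed(spec$seed, {
    recs <- list()
    for (group in c("trained", "control")) {
      for (k in seq_len(spec$n_per_group)) {
        id <- sprintf("%s%03d", if (group == "trained") "T" else "C", k)
        recs[[id]] <- draw_subject(spec, group, id, chols[[group]])
      }
    }
    recs
  })
  groups <- vapply(subjects, `[[`, "", "group")
  conns <- vapply(subjects, `[[`, 0, "planted_connectivity")
  trained_idx <- which(groups == "trained")
  standardizer <- list(
    mean = mean(conns[trained_idx]),
    sd = stats::sd(conns[trained_idx])
  )
  for (i in seq_along(subjects)) {
    subjects[[i]]$behavior_score <- score_subject(
      spec, groups[i], conns[i], subjects[[i]]$score_noise_z,
      standardizer
    )
    subjects[[i]]$score_noise_z <- NULL
  }
  manifest <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    group = groups,
    behavior_score = vapply(subjects, `[[`, 0, "behavior_score"),
    row.names = NULL
  )
  structure(list(subjects = subjects, manifest = manifest, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects (%d trained / %d control), %d regions x %d timepoints\n",
    nrow(x$manifest), sum(x$manifest$group == "trained"),
    sum(x$manifest$group == "control"), x$spec$n_regions, x$spec$n_timepoints
  ))
  invisible(x)
}
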