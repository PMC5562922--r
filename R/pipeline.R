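#' Analysis configuration
#'
#' Collects every tunable of the end-to-end analysis.  Defaults follow the
#' protocol this pipeline implements: density sweep 24.5%--30% in steps
#' of 0.005, 1000 degree-matched random networks behind the normalized
#' global metrics, 10000 permutations for group comparisons, and FDR at
#' q = 0.05 over the nodes of each nodal metric.
#'
#' @param sweep_mode `"fixed"` uses `d_min`/`d_max`/`step` as given;
#'   `"auto"` derives `d_min` by [find_min_connected_density()] and `d_max`
#'   by [find_max_density_fdr()] (rounded down to the grid).
#' @param d_min,d_max,step sweep endpoints and interval.
#' @param rank edge ranking, `"signed"` or `"absolute"`.
#' @param le_variant local-efficiency form, `"harmonic"` or `"inverse_mean"`.
#' @param nodal_metrics which nodal metrics to test between groups.
#' @param global_metrics compute global `C`/`L` curves and their group
#'   tests; disable for nodal-only runs (global path length needs connected
#'   networks, which small sparse cohorts may not provide at every density).
#' @param ensemble_size random networks behind `C_nor`/`L_nor`; 0 skips
#'   global-metric normalization.
#' @param null_model `"rewire"` or `"gnm"` ensemble, see
#'   [normalized_global_metrics()].
#' @param n_perm permutations for group tests.
#' @param q FDR level for the node-wise correction and the FDR density rule.
#' @param seed root RNG seed; stage seeds are derived from it so stages are
#'   independently reproducible.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(sweep_mode = c("fixed", "auto"),
                            d_min = 0.245, d_max = 0.300, step = 0.005,
                            rank = c("signed", "absolute"),
                            le_variant = c("harmonic", "inverse_mean"),
                            nodal_metrics = c("degree", "local_efficiency"),
                            global_metrics = TRUE,
                            ensemble_size = 1000,
                            null_model = c("rewire", "gnm"),
                            n_perm = 10000, q = 0.05, seed = 1L) {
  structure(
    list(
      sweep_mode = match.arg(sweep_mode),
      d_min = d_min, d_max = d_max, step = step,
      rank = match.arg(rank),
      le_variant = match.arg(le_variant),
      nodal_metrics = match.arg(nodal_metrics, several.ok = TRUE),
      global_metrics = isTRUE(global_metrics),
      ensemble_size = ensemble_size,
      null_model = match.arg(null_model),
      n_perm = n_perm, q = q, seed = as.integer(seed)
    ),
    class = "analysis_config"
  )
}

# Per-stage seeds derived from the root seed by fixed offsets, so e.g. the
# permutation stage can be rerun alone with an identical stream.
stage_seed <- function(config, stage) {
  offsets <- c(ensemble = 101L, permutation = 202L)
  (config$seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full group analysis on a cohort
#'
#' Executes the complete chain on an in-memory cohort (or a directory
#' written by [write_cohort()]): Pearson connectivity per subject; sweep
#' endpoints (fixed or data-derived); binary networks across the density
#' grid; nodal metric curves and their AUCs; global `C` and `L` (optionally
#' normalized against rewired null ensembles) and their AUCs; node-wise
#' permutation tests with Benjamini-Hochberg correction per metric;
#' global-metric permutation tests; and within-group Pearson correlations
#' between nodal AUCs and behavioral scores.
#'
#' @param cohort a `cohort`, or a directory path for [read_cohort()].
#' @param config an [analysis_config()].
#' @param verbose print stage progress.
#' @return An `analysis_result` list with elements `sweep`,
#'   `nodal_auc` (per metric: subjects x nodes matrix), `global_auc`
#'   (per metric: named per-subject vector), `group_tests` (per metric:
#'   observed differences, p-values, FDR mask), `global_tests`,
#'   `behavior` (per metric/group: per-node r and p),
#'   `disconnected_subjects`, and the echoed `config`.
#' @export
analyze_cohort <- function(cohort, config = analysis_config(),
                           verbose = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "cohort"))
  subjects <- cohort$subjects
  manifest <- cohort$manifest
  say <- function(...) if (verbose) message(sprintf(...))

  say("connectivity: %d subjects", length(subjects))
  cms <- lapply(subjects, pearson_connectivity)

  if (config$sweep_mode == "auto") {
    d_min <- find_min_connected_density(cms, config$step, config$rank)
    frac <- find_max_density_fdr(cms, config$q)
    d_max <- floor(frac / config$step) * config$step
    say("auto sweep endpoints: d_min=%.3f, FDR fraction=%.4f -> d_max=%.3f",
        d_min, frac, d_max)
    if (d_max <= d_min) {
      stop(sprintf(
        paste0("endpoint rules conflict: minimum connected density %.3f is ",
               "not below the FDR-significant density %.4f; no sweep range ",
               "exists where networks are both connected and fully ",
               "FDR-supported. Use a fixed sweep (sweep_mode = 'fixed')."),
        d_min, frac
      ))
    }
  } else {
    d_min <- config$d_min
    d_max <- config$d_max
  }
  sweep <- density_sweep(d_min, d_max, config$step)
  nd <- length(sweep$densities)
  n_nodes <- nrow(cms[[1]]$r)
  node_names <- rownames(cms[[1]]$r) %||% sprintf("R%03d", seq_len(n_nodes))

  say("metrics: %d densities x %d nodes", nd, n_nodes)
  want_global <- config$global_metrics %||% TRUE
  nodal_auc <- lapply(config$nodal_metrics, function(m) {
    matrix(NA_real_, length(subjects), n_nodes,
           dimnames = list(names(subjects), node_names))
  })
  names(nodal_auc) <- config$nodal_metrics
  global_names <- if (want_global) {
    c("C", "L", if (config$ensemble_size > 0) c("C_nor", "L_nor"))
  } else {
    character(0)
  }
  global_auc <- lapply(global_names, function(m) {
    stats::setNames(rep(NA_real_, length(subjects)), names(subjects))
  })
  names(global_auc) <- global_names
  disconnected <- character(0)

  ens_seed <- stage_seed(config, "ensemble")
  for (si in seq_along(subjects)) {
    nets <- build_sweep_networks(cms[[si]], sweep, config$rank)
    curves <- lapply(config$nodal_metrics, function(m) {
      matrix(NA_real_, nd, n_nodes)
    })
    names(curves) <- config$nodal_metrics
    gcurves <- sapply(global_names, function(m) rep(NA_real_, nd),
                      simplify = FALSE)
    for (di in seq_len(nd)) {
      net <- nets[[di]]
      if ("degree" %in% config$nodal_metrics) {
        curves$degree[di, ] <- node_degree(net)
      }
      if ("local_efficiency" %in% config$nodal_metrics) {
        curves$local_efficiency[di, ] <-
          local_efficiency(net, variant = config$le_variant)
      }
      if ("clustering" %in% config$nodal_metrics) {
        curves$clustering[di, ] <- clustering_coefficient(net)
      }
      if (want_global) {
        gm <- withCallingHandlers(
          global_metrics(net),
          warning = function(w) invokeRestart("muffleWarning")
        )
        if (!gm$connected) {
          disconnected <- union(disconnected, names(subjects)[si])
        }
        gcurves$C[di] <- gm$C
        gcurves$L[di] <- gm$L
        if (config$ensemble_size > 0) {
          nor <- normalized_global_metrics(
            net, config$ensemble_size,
            seed = (ens_seed + 1000L * si + di) %% .Machine$integer.max,
            null = config$null_model
          )
          gcurves$C_nor[di] <- nor$C_nor
          gcurves$L_nor[di] <- nor$L_nor
        }
      }
    }
    for (m in config$nodal_metrics) {
      nodal_auc[[m]][si, ] <- apply(curves[[m]], 2, curve_auc,
                                    densities = sweep$densities)
    }
    for (m in global_names) {
      global_auc[[m]][si] <- curve_auc(gcurves[[m]], sweep$densities)
    }
    if (verbose && si %% 25 == 0) say("  subject %d/%d", si, length(subjects))
  }
  if (length(disconnected)) {
    warning("disconnected network(s) within the sweep for subject(s): ",
            paste(disconnected, collapse = ", "))
  }

  say("group inference: %d permutations", config$n_perm)
  is_a <- manifest$group == "trained"
  perm_seed <- stage_seed(config, "permutation")
  group_tests <- lapply(seq_along(config$nodal_metrics), function(mi) {
    m <- config$nodal_metrics[mi]
    pt <- permutation_group_test_matrix(
      nodal_auc[[m]][is_a, , drop = FALSE],
      nodal_auc[[m]][!is_a, , drop = FALSE],
      n_perm = config$n_perm,
      seed = (perm_seed + mi) %% .Machine$integer.max
    )
    data.frame(
      node = node_names,
      observed_diff = pt$observed_diff,
      p = pt$p_two_tailed,
      fdr_significant = fdr_bh(pt$p_two_tailed, config$q),
      row.names = NULL
    )
  })
  names(group_tests) <- config$nodal_metrics

  global_tests <- lapply(seq_along(global_names), function(mi) {
    m <- global_names[mi]
    pt <- permutation_group_test(
      global_auc[[m]][is_a], global_auc[[m]][!is_a],
      n_perm = max(config$n_perm, 100),
      seed = (perm_seed + 100L + mi) %% .Machine$integer.max
    )
    list(metric = m, observed_diff = pt$observed_diff, p = pt$p_two_tailed,
         mean_sd = list(
           trained = c(mean = mean(global_auc[[m]][is_a]),
                       sd = stats::sd(global_auc[[m]][is_a])),
           control = c(mean = mean(global_auc[[m]][!is_a]),
                       sd = stats::sd(global_auc[[m]][!is_a]))
         ))
  })
  names(global_tests) <- global_names

  behavior <- lapply(config$nodal_metrics, function(m) {
    lapply(c(trained = "trained", control = "control"), function(g) {
      sel <- manifest$group == g
      res <- apply(nodal_auc[[m]][sel, , drop = FALSE], 2, function(v) {
        if (sum(sel) < 4 || stats::var(v) == 0) {
          return(c(r = NA_real_, p = NA_real_))
        }
        bc <- behavior_correlation(v, manifest$behavior_score[sel])
        c(r = bc$r, p = bc$p)
      })
      data.frame(node = node_names, r = res["r", ], p = res["p", ],
                 row.names = NULL)
    })
  })
  names(behavior) <- config$nodal_metrics

  structure(
    list(sweep = sweep, nodal_auc = nodal_auc, global_auc = global_auc,
         group_tests = group_tests, global_tests = global_tests,
         behavior = behavior, disconnected_subjects = disconnected,
         manifest = manifest, config = config),
    class = "analysis_result"
  )
}

#' Write analysis outputs to a directory
#'
#' Emits `report.json` (group tests, global tests, behavior correlations,
#' sweep, config echo), plus TSV tables of the per-subject AUCs.
#'
#' @param result an `analysis_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "analysis_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    sweep = result$sweep[c("d_min", "d_max", "step", "densities")],
    config = unclass(result$config),
    group_tests = result$group_tests,
    global_tests = result$global_tests,
    behavior = result$behavior,
    disconnected_subjects = result$disconnected_subjects
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (m in names(result$nodal_auc)) {
    df <- data.frame(subject_id = rownames(result$nodal_auc[[m]]),
                     result$nodal_auc[[m]], check.names = FALSE)
    utils::write.table(df, file.path(dir, sprintf("auc_%s.tsv", m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(result$global_auc)) {
    gdf <- data.frame(subject_id = names(result$global_auc[[1]]),
                      as.data.frame(result$global_auc))
    utils::write.table(gdf, file.path(dir, "auc_global.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Human-readable summary of an analysis
#'
#' Prints the sweep, global-metric group means (AUC +/- SD) with permutation
#' p-values, the FDR-significant nodes per nodal metric ordered by p then
#' node index (or an explicit "none"), and within-group behavior
#' correlations at the significant nodes.
#'
#' @param result an `analysis_result`.
#' @param file optional path; when given, the summary is also written there.
#' @return The summary lines, invisibly.
#' @export
report_summary <- function(result, file = NULL) {
  lines <- c(sprintf("Density sweep: %.3f..%.3f step %.3f (%d densities)",
                     result$sweep$d_min, result$sweep$d_max,
                     result$sweep$step, length(result$sweep$densities)),
             "", "Global metrics (AUC over sweep):")
  for (m in names(result$global_tests)) {
    gt <- result$global_tests[[m]]
    lines <- c(lines, sprintf(
      "  %-6s trained %.4g +/- %.2g | control %.4g +/- %.2g | perm p = %.4g",
      m, gt$mean_sd$trained["mean"], gt$mean_sd$trained["sd"],
      gt$mean_sd$control["mean"], gt$mean_sd$control["sd"], gt$p
    ))
  }
  for (m in names(result$group_tests)) {
    gt <- result$group_tests[[m]]
    sig <- gt[gt$fdr_significant, , drop = FALSE]
    sig <- sig[order(sig$p, sig$node), , drop = FALSE]
    lines <- c(lines, "", sprintf("Nodal %s: FDR-significant nodes (q = %g):",
                                  m, result$config$q))
    if (nrow(sig) == 0) {
      lines <- c(lines, "  none")
    } else {
      for (i in seq_len(nrow(sig))) {
        beh <- result$behavior[[m]]$trained
        bi <- beh[beh$node == sig$node[i], ]
        lines <- c(lines, sprintf(
          "  %-6s diff = %+.4g, p = %.4g | trained behavior r = %.2f (p = %.3g)",
          sig$node[i], sig$observed_diff[i], sig$p[i], bi$r, bi$p
        ))
      }
    }
  }
  if (length(result$disconnected_subjects)) {
    lines <- c(lines, "", paste("Disconnected within sweep:",
                                paste(result$disconnected_subjects,
                                      collapse = ", ")))
  }
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' @export
print.analysis_result <- function(x, ...) {
  report_summary(x)
  invisible(x)
}
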