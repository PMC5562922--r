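# Cohort serialization: one TSV per subject (rows = regions, first column =
# region label, remaining columns = timepoints), a manifest TSV, and the
# cohort spec echoed as YAML.

#' Write a cohort to a directory
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$subjects) {
    df <- data.frame(region = rownames(rec$timeseries), rec$timeseries,
                     check.names = FALSE)
    colnames(df) <- c("region", sprintf("t%d", seq_len(ncol(rec$timeseries))))
    utils::write.table(df, file.path(dir, paste0(rec$subject_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- cohort$spec
  spec_list <- lapply(unclass(spec), function(x) {
    if (is.null(x)) NULL else unname(x)
  })
  spec_list$behavior_mean_by_group <- as.list(spec$behavior_mean_by_group)
  spec_list$behavior_sd_by_group <- as.list(spec$behavior_sd_by_group)
  yaml::write_yaml(spec_list, file.path(dir, "cohort_spec.yaml"))
  invisible(dir)
}

#' Read a cohort from a directory
#'
#' Reads the manifest and the per-subject time-series TSVs written by
#' [write_cohort()] (or any conforming real data: a `manifest.tsv` with
#' columns subject_id/group/behavior_score and one `<subject_id>.tsv` per
#' row, regions x timepoints with a leading region-label column).
#'
#' @param dir cohort directory.
#' @return A `cohort` (with `spec = NULL` unless `cohort_spec.yaml` exists).
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) stop("no manifest.tsv in ", dir)
  manifest <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$subject_id[i]
    path <- file.path(dir, paste0(id, ".tsv"))
    if (!file.exists(path)) stop("missing time-series file: ", path)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    ts <- as.matrix(df[, -1, drop = FALSE])
    rownames(ts) <- df[[1]]
    if (anyNA(ts)) stop("missing values in ", path)
    structure(
      list(subject_id = id, group = manifest$group[i], timeseries = ts,
           behavior_score = manifest$behavior_score[i],
           planted_connectivity = NA_real_),
      class = "subject_record"
    )
  })
  names(subjects) <- manifest$subject_id
  spec <- NULL
  spec_path <- file.path(dir, "cohort_spec.yaml")
  if (file.exists(spec_path)) spec <- yaml::read_yaml(spec_path)
  structure(list(subjects = subjects, manifest = manifest, spec = spec),
            class = "cohort")
}
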