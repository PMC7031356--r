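# End-to-end orchestration: simulate -> stratify -> connectivity -> analyze,
# with a YAML run config, frozen provenance, and deterministic on-disk
# artifacts. Stages communicate only through files, so any stage can be
# re-run from its on-disk inputs.

#' Default run configuration
#'
#' @return Named list of defaults (a small demo-sized cohort).
#' @export
default_run_config <- function() {
  list(seed = 0L, n_subjects = 48L, n_regions = 20L, n_timepoints = 200L,
       beta = 6, alpha = 0.05, ss_type = 3,
       criteria = c("total", "deep", "periventricular"),
       base_correlation = 0.2, background_correlation = 0.1,
       effect_node = 1L, n_effect_neighbors = 3L,
       obesity_main_delta = 0, interaction_delta = 0,
       confound_age_slope = 0, confound_sex_delta = 0)
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; missing keys fall back to
#' [default_run_config()].
#'
#' @param path YAML file path.
#' @return Resolved config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defs <- default_run_config()
  unknown <- setdiff(names(cfg), names(defs))
  if (length(unknown))
    stop("read_run_config: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  utils::modifyList(defs, cfg)
}

config_to_spec <- function(cfg) {
  cohort_spec(n_subjects = cfg$n_subjects, n_regions = cfg$n_regions,
              n_timepoints = cfg$n_timepoints, seed = cfg$seed,
              base_correlation = cfg$base_correlation,
              background_correlation = cfg$background_correlation,
              effect_node = cfg$effect_node,
              n_effect_neighbors = cfg$n_effect_neighbors,
              obesity_main_delta = cfg$obesity_main_delta,
              interaction_delta = cfg$interaction_delta,
              confound_age_slope = cfg$confound_age_slope,
              confound_sex_delta = cfg$confound_sex_delta)
}

#' Write the subject table CSV
#' @param subjects Subject data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_subjects_csv <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject table CSV
#' @param path CSV path.
#' @return data.frame.
#' @export
read_subjects_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the full pipeline from a configuration
#'
#' Simulates a cohort, writes all artifacts (subject table, per-subject
#' time-series TSVs with a manifest, group assignments, cell counts,
#' centrality table, ANOVA and post-hoc results, run summary, and a frozen
#' copy of the resolved config) into `out_dir`. Output content is a
#' deterministic function of the config (including its seed).
#'
#' @param config Config list (see [default_run_config()]) or a YAML path.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the in-memory result bundle (list per criterion plus
#'   subjects/assignments).
#' @export
run_full <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_run_config(config) else
    utils::modifyList(default_run_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ts_dir <- file.path(out_dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)

  spec <- config_to_spec(cfg)
  cohort <- generate_subjects(spec)
  ts <- generate_timeseries(spec, cohort$labels, subjects = cohort$subjects)

  write_subjects_csv(cohort$subjects, file.path(out_dir, "subjects.csv"))
  manifest <- data.frame(
    subject_id = vapply(ts, function(x) x$subject_id, character(1)),
    file = vapply(ts, function(x) paste0(x$subject_id, ".tsv"),
                  character(1)), stringsAsFactors = FALSE)
  for (x in ts) write_timeseries_tsv(x, file.path(ts_dir, paste0(
    x$subject_id, ".tsv")))
  utils::write.csv(manifest, file.path(out_dir, "timeseries_manifest.csv"),
                   row.names = FALSE, quote = FALSE)

  asg <- assign_groups(cohort$subjects, criteria = cfg$criteria)
  utils::write.csv(asg, file.path(out_dir, "assignments.csv"),
                   row.names = FALSE, quote = FALSE)
  counts <- cell_counts(asg)
  jsonlite::write_json(counts, file.path(out_dir, "cell_counts.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  cmat <- centrality_matrix(ts, beta = cfg$beta)
  adj <- adjust_covariates(cmat, cohort$subjects$age, cohort$subjects$sex)
  long <- data.frame(
    subject_id = rep(rownames(cmat), times = ncol(cmat)),
    region_id = rep(colnames(cmat), each = nrow(cmat)),
    raw = as.vector(cmat), adjusted = as.vector(adj$adjusted),
    stringsAsFactors = FALSE)
  utils::write.csv(long, file.path(out_dir, "centrality.csv"),
                   row.names = FALSE, quote = FALSE)

  res <- run_analysis(asg, adj$adjusted, criteria = cfg$criteria,
                      alpha = cfg$alpha, ss_type = cfg$ss_type)
  utils::write.csv(res$anova, file.path(out_dir, "anova_results.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(res$posthoc, file.path(out_dir, "posthoc_results.csv"),
                   row.names = FALSE, quote = FALSE)

  an_int <- res$anova[res$anova$effect == "interaction", ]
  top <- an_int[order(an_int$criterion, -an_int$F), ]
  top <- top[!duplicated(top$criterion),
             c("criterion", "region_id", "F", "p", "q")]
  summary <- list(
    package_version = as.character(utils::packageVersion("wmhconnect")),
    seed = cfg$seed, parameters = cfg,
    cell_counts = counts, top_interaction_nodes = top,
    n_significant_interactions = sum(an_int$q < cfg$alpha))
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))

  invisible(list(config = cfg, subjects = cohort$subjects,
                 labels = cohort$labels, assignments = asg,
                 centrality = cmat, adjusted = adj$adjusted, results = res))
}
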