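# Monte-Carlo calibration and power/recovery harnesses for the full
# node-level pipeline (generator -> stratification -> connectivity ->
# adjustment -> factorial ANOVA). Used both by the acceptance tests and by
# scripts/acceptance.R.

#' Run the full node-level pipeline on one synthetic cohort
#'
#' Generates subjects and series from `spec`, stratifies by the chosen
#' criterion, computes age/sex-adjusted degree centrality, and returns the
#' per-node ANOVA table plus intermediate objects.
#'
#' @param spec A [cohort_spec()].
#' @param criterion WMH criterion used for stratification.
#' @param beta Scale-free index.
#' @param ss_type Sums-of-squares type.
#' @return List: subjects, labels, assignments, centrality (raw),
#'   adjusted, anova (with q per effect).
#' @export
run_pipeline_once <- function(spec, criterion = "total", beta = 6,
                              ss_type = 3) {
  cohort <- generate_subjects(spec)
  ts <- generate_timeseries(spec, cohort$labels, subjects = cohort$subjects)
  asg <- assign_groups(cohort$subjects, criteria = criterion)
  cmat <- centrality_matrix(ts, beta = beta)
  adj <- adjust_covariates(cmat, cohort$subjects$age, cohort$subjects$sex)
  cells <- asg$cell[match(rownames(cmat), asg$subject_id)]
  an <- two_way_anova(adj$adjusted, cells, ss_type = ss_type)
  an$q <- NA_real_
  for (eff in unique(an$effect))
    an$q[an$effect == eff] <- fdr_correct(an$p[an$effect == eff])
  list(subjects = cohort$subjects, labels = cohort$labels,
       assignments = asg, centrality = cmat, adjusted = adj$adjusted,
       cells = cells, anova = an)
}

#' Type-I error and FDR calibration under the global null
#'
#' Repeatedly simulates cohorts with no implanted effects (all deltas 0),
#' runs the full pipeline, and records the per-node interaction-test
#' rejection rate at `alpha` (uncorrected) and the realised false-discovery
#' proportion after BH correction over nodes. Under a valid pipeline the
#' rejection rate should sit at `alpha` and the mean FDP at or below it.
#'
#' @param n_reps Replicate cohorts.
#' @param n_subjects,n_regions,n_timepoints Cohort dimensions per replicate.
#' @param alpha Nominal level.
#' @param seed Base seed; replicate r uses seed + r.
#' @return List: rejection_rate, mean_fdp, n_tests, n_reps.
#' @export
calibrate_null <- function(n_reps = 2000, n_subjects = 48, n_regions = 10,
                           n_timepoints = 150, alpha = 0.05, seed = 20260101) {
  rejections <- 0L; n_tests <- 0L; fdp <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    spec <- cohort_spec(n_subjects = n_subjects, n_regions = n_regions,
                        n_timepoints = n_timepoints,
                        seed = (seed + r * 2L) %% .Machine$integer.max,
                        obesity_main_delta = 0, interaction_delta = 0)
    res <- run_pipeline_once(spec)
    p_int <- res$anova$p[res$anova$effect == "interaction"]
    q_int <- res$anova$q[res$anova$effect == "interaction"]
    rejections <- rejections + sum(p_int < alpha)
    n_tests <- n_tests + length(p_int)
    n_disc <- sum(q_int < alpha)
    fdp[r] <- if (n_disc > 0) 1 else 0  # all discoveries false under null
  }
  list(rejection_rate = rejections / n_tests, mean_fdp = mean(fdp),
       n_tests = n_tests, n_reps = n_reps)
}

#' Recovery of an implanted interaction node
#'
#' Simulates cohorts carrying a large hw-o-only correlation increase at one
#' node and measures how often that node is the top-ranked interaction hit
#' (largest interaction F) after the full pipeline.
#'
#' @param n_runs Number of seeded runs.
#' @param interaction_delta Implanted correlation increment.
#' @param base_correlation Effect-edge correlation in the reference cell.
#' @param n_subjects,n_regions,n_timepoints Cohort dimensions.
#' @param seed Base seed; run r uses seed + r.
#' @return List: top_rate (fraction of runs with the implanted node ranked
#'   first), n_runs, effect_node.
#' @export
recover_interaction_node <- function(n_runs = 100, interaction_delta = 0.4,
                                     base_correlation = 0.2,
                                     n_subjects = 182, n_regions = 10,
                                     n_timepoints = 490, seed = 20260401) {
  hits <- logical(n_runs)
  effect_node <- 5L
  for (r in seq_len(n_runs)) {
    spec <- cohort_spec(n_subjects = n_subjects, n_regions = n_regions,
                        n_timepoints = n_timepoints,
                        seed = (seed + r * 2L) %% .Machine$integer.max,
                        effect_node = effect_node,
                        base_correlation = base_correlation,
                        interaction_delta = interaction_delta)
    res <- run_pipeline_once(spec)
    an_int <- res$anova[res$anova$effect == "interaction", ]
    top <- an_int$region_id[which.max(an_int$F)]
    hits[r] <- identical(top, colnames(res$centrality)[effect_node])
  }
  list(top_rate = mean(hits), n_runs = n_runs, effect_node = effect_node)
}
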