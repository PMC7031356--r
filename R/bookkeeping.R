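# Self-contained count arithmetic of the study design: candidate-to-analyzed
# cohort flow and independent-component node bookkeeping. Kept as real,
# validated functions so the design's arithmetic claims are executable.

#' Cohort exclusion flow
#'
#' Applies sequential, disjoint exclusion steps to a candidate pool and
#' returns the analyzed sample size with a step-by-step table. Defaults
#' encode the motivating cohort: 13,718 candidates; 91 lacking waist, hip,
#' or BMI measurements; 29 lacking one of the three imaging modalities;
#' 13,416 without any white-matter hyperintensities.
#'
#' @param candidates Number of candidate subjects.
#' @param exclusions Named numeric vector of exclusion counts, applied in
#'   order and assumed disjoint.
#' @return List with `analyzed` (final n) and `steps` (data.frame: step,
#'   excluded, remaining).
#' @examples
#' cohort_flow()$analyzed  # 182
#' @export
cohort_flow <- function(candidates = 13718,
                        exclusions = c(missing_anthropometry = 91,
                                       missing_imaging = 29,
                                       no_wmh = 13416)) {
  if (candidates < 0 || any(exclusions < 0))
    stop("cohort_flow: counts must be non-negative")
  if (sum(exclusions) > candidates)
    stop("cohort_flow: exclusions exceed the candidate pool")
  remaining <- candidates - cumsum(exclusions)
  list(analyzed = as.integer(candidates - sum(exclusions)),
       steps = data.frame(step = names(exclusions),
                          excluded = as.integer(exclusions),
                          remaining = as.integer(remaining),
                          stringsAsFactors = FALSE))
}

#' Analysis-node bookkeeping for ICA-derived graphs
#'
#' Number of graph nodes left after removing noise components from a set of
#' independent components (defaults: 42 generated, 7 noise, 35 analyzed).
#'
#' @param n_components Components generated.
#' @param n_noise Components flagged as noise.
#' @return Integer count of analysis nodes.
#' @export
ic_analysis_nodes <- function(n_components = 42, n_noise = 7) {
  if (n_noise > n_components)
    stop("ic_analysis_nodes: more noise components than components")
  if (n_components < 0 || n_noise < 0)
    stop("ic_analysis_nodes: counts must be non-negative")
  as.integer(n_components - n_noise)
}
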