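#' Cohort specification for the synthetic factorial generator
#'
#' A `cohort_spec` freezes every parameter of the synthetic world: cohort
#' size and 2x2 cell structure, demographics, anthropometry, lesion-volume
#' distributions, and the block correlation structure of the region time
#' series (including the implantable obesity main effect and the
#' WMH-by-obesity interaction at one designated node).
#'
#' Defaults reproduce the cohort the analysis was designed around: 182
#' subjects, 35 nodes, 490 timepoints, age 55.21 (SD 7.16) years, 100:82
#' male:female, right-skewed lognormal WMH volumes whose low/high-burden
#' components match the observed cell means, and waist-hip ratios drawn
#' relative to the sex-specific obesity cutoffs (>0.90 male, >0.85 female)
#' so the stratification rule recovers the generating labels.
#'
#' @param n_subjects Number of subjects; must be >= 8 and divide into four
#'   nonempty cells.
#' @param n_regions Number of graph nodes R.
#' @param n_timepoints Number of timepoints T per subject (>= 3).
#' @param seed Optional integer seed; seeded runs are bit-reproducible.
#' @param age_mean,age_sd Age distribution (years).
#' @param male_fraction Proportion of males.
#' @param whr_params List with `nonobese_offset`, `obese_offset`, `sd`:
#'   waist-hip ratio is drawn as sex cutoff + offset + Normal(0, sd), so the
#'   obese/non-obese labels are recoverable by the classification rule.
#' @param wmh_lognormal_params List with `low` and `high` elements, each a
#'   list `meanlog`/`sdlog` for the total WMH volume (mm^3) of the
#'   low/high-burden groups.
#' @param peri_fraction_beta List `mean`/`concentration` of the Beta
#'   distribution for the periventricular fraction of total WMH volume
#'   (deep = total - periventricular).
#' @param base_correlation Correlation between the effect node and its
#'   neighbour set in the reference (lw-no) cell; in (-1, 1).
#' @param background_correlation Correlation of every other region pair.
#' @param effect_node Index of the node carrying the implanted effects.
#' @param n_effect_neighbors Size of the effect node's neighbour set (the
#'   next `n_effect_neighbors` node indices, cyclically).
#' @param obesity_main_delta Correlation increment on effect edges for all
#'   obese subjects (main effect of obesity).
#' @param interaction_delta Additional correlation increment on effect edges
#'   only in the high-burden obese (hw-o) cell (the interaction).
#' @param noise_sd Marginal standard deviation of each region signal
#'   (signal units; must be > 0 so no column is constant).
#' @param confound_age_slope,confound_sex_delta Uniform off-diagonal
#'   correlation shift per year of age (centred) and for males, used to make
#'   the downstream age/sex residualisation falsifiable. Default 0.
#' @return An object of class `cohort_spec` (a validated list).
#' @examples
#' spec <- cohort_spec(n_subjects = 8, n_regions = 5, n_timepoints = 50,
#'                     seed = 1)
#' spec$n_subjects
#' @export
cohort_spec <- function(n_subjects = 182,
                        n_regions = 35,
                        n_timepoints = 490,
                        seed = NULL,
                        age_mean = 55.21,
                        age_sd = 7.16,
                        male_fraction = 100 / 182,
                        whr_params = list(nonobese_offset = -0.06,
                                          obese_offset = 0.05,
                                          sd = 0.03),
                        wmh_lognormal_params = list(
                          low  = list(meanlog = 6.96, sdlog = 0.41),
                          high = list(meanlog = 8.35, sdlog = 0.63)),
                        peri_fraction_beta = list(mean = 0.87,
                                                  concentration = 20),
                        base_correlation = 0.2,
                        background_correlation = 0.1,
                        effect_node = 1L,
                        n_effect_neighbors = 3L,
                        obesity_main_delta = 0,
                        interaction_delta = 0,
                        noise_sd = 1,
                        confound_age_slope = 0,
                        confound_sex_delta = 0) {
  spec <- structure(
    list(n_subjects = as.integer(n_subjects),
         n_regions = as.integer(n_regions),
         n_timepoints = as.integer(n_timepoints),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         age_mean = age_mean, age_sd = age_sd,
         male_fraction = male_fraction,
         whr_params = whr_params,
         wmh_lognormal_params = wmh_lognormal_params,
         peri_fraction_beta = peri_fraction_beta,
         base_correlation = base_correlation,
         background_correlation = background_correlation,
         effect_node = as.integer(effect_node),
         n_effect_neighbors = as.integer(n_effect_neighbors),
         obesity_main_delta = obesity_main_delta,
         interaction_delta = interaction_delta,
         noise_sd = noise_sd,
         confound_age_slope = confound_age_slope,
         confound_sex_delta = confound_sex_delta),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks range invariants and, crucially, that every correlation matrix the
#' spec implies (one per factorial cell) is positive semi-definite; a spec
#' that implies a non-PSD matrix is rejected with a diagnostic naming the
#' offending parameter.
#'
#' @param spec A `cohort_spec`.
#' @return The spec, invisibly, if valid; otherwise an error.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_subjects < 8L)
    stop("invalid cohort_spec: n_subjects must be >= 8 (got ",
         spec$n_subjects, ")")
  if (spec$n_timepoints < 3L)
    stop("invalid cohort_spec: n_timepoints must be >= 3")
  if (spec$n_regions < 2L)
    stop("invalid cohort_spec: n_regions must be >= 2")
  if (spec$noise_sd <= 0)
    stop("invalid cohort_spec: noise_sd must be > 0")
  if (spec$male_fraction < 0 || spec$male_fraction > 1)
    stop("invalid cohort_spec: male_fraction must be in [0, 1]")
  if (spec$effect_node < 1L || spec$effect_node > spec$n_regions)
    stop("invalid cohort_spec: effect_node out of range 1..n_regions")
  if (spec$n_effect_neighbors < 1L ||
      spec$n_effect_neighbors > spec$n_regions - 1L)
    stop("invalid cohort_spec: n_effect_neighbors must be in 1..n_regions-1")
  for (p in c("base_correlation", "background_correlation",
              "obesity_main_delta", "interaction_delta")) {
    if (abs(spec[[p]]) >= 1)
      stop("invalid cohort_spec: ", p, " must lie in (-1, 1)")
  }
  # every implied cell-level correlation matrix must be PSD
  for (cell in cell_levels()) {
    sigma <- cell_correlation_matrix(spec, cell)
    ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      bad <- if (cell == "hw-o" && spec$interaction_delta != 0)
        "interaction_delta" else if (grepl("-o$", cell) &&
                                     spec$obesity_main_delta != 0)
        "obesity_main_delta" else "base_correlation/background_correlation"
      stop("invalid cohort_spec: implied correlation matrix for cell '",
           cell, "' is not positive semi-definite (min eigenvalue ",
           format(ev, digits = 3), "); check ", bad)
    }
  }
  invisible(spec)
}

#' Four factorial cell labels in canonical order
#' @return Character vector `c("lw-no", "lw-o", "hw-no", "hw-o")`.
#' @export
cell_levels <- function() c("lw-no", "lw-o", "hw-no", "hw-o")

#' Effect-node neighbour set implied by a spec
#' @param spec A `cohort_spec`.
#' @return Integer vector of neighbour node indices (cyclic successors of
#'   `effect_node`).
#' @export
effect_neighbors <- function(spec) {
  idx <- (spec$effect_node + seq_len(spec$n_effect_neighbors) - 1L) %%
    spec$n_regions + 1L
  idx
}

#' Correlation matrix implied by a spec for one factorial cell
#'
#' Off-diagonal entries are `background_correlation` except on edges between
#' the effect node and its neighbour set, which carry
#' `base_correlation + obesity_main_delta` (obese cells)
#' `+ interaction_delta` (hw-o cell only). An optional uniform shift models
#' the age/sex confound.
#'
#' @param spec A `cohort_spec`.
#' @param cell One of `cell_levels()`.
#' @param shift Uniform off-diagonal increment (confound), default 0.
#' @return R x R correlation matrix.
#' @export
cell_correlation_matrix <- function(spec, cell, shift = 0) {
  cell <- match.arg(cell, cell_levels())
  R <- spec$n_regions
  rho <- spec$background_correlation
  sigma <- matrix(rho, R, R)
  r_eff <- spec$base_correlation
  if (cell %in% c("lw-o", "hw-o")) r_eff <- r_eff + spec$obesity_main_delta
  if (cell == "hw-o") r_eff <- r_eff + spec$interaction_delta
  nb <- effect_neighbors(spec)
  sigma[spec$effect_node, nb] <- r_eff
  sigma[nb, spec$effect_node] <- r_eff
  if (shift != 0) sigma <- sigma + shift * (1 - diag(R))
  sigma <- pmin(pmax(sigma, -0.999), 0.999)
  diag(sigma) <- 1
  sigma
}
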