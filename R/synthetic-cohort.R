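#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic subject table with true factorial labels
#'
#' Draws `n_subjects` subjects assigned as evenly as possible to the four
#' WMH-burden-by-obesity cells. Age is Normal(age_mean, age_sd); sex is
#' Bernoulli(male_fraction). Waist-hip ratio is drawn relative to the
#' subject's sex-specific obesity cutoff (0.90 male / 0.85 female) plus the
#' group offset, so the classification rule recovers the true obesity label
#' for the vast majority of subjects; hip circumference is
#' Normal(103.21, 7.67) cm and waist = WHR x hip. Total WMH volume is
#' lognormal per burden group (strong right skew, SD of the order of the
#' mean); the periventricular share is Beta-distributed and deep +
#' periventricular volumes sum exactly to the total.
#'
#' @param spec A validated [cohort_spec()].
#' @return A list with `subjects` (data.frame: subject_id, age, sex,
#'   waist_cm, hip_cm, bmi, wmh_total_mm3, wmh_deep_mm3, wmh_peri_mm3) and
#'   `labels` (data.frame: subject_id, true_wmh, true_obesity, true_cell).
#' @examples
#' cohort <- generate_subjects(cohort_spec(n_subjects = 8, n_regions = 5,
#'                                         n_timepoints = 50, seed = 1))
#' table(cohort$labels$true_cell)
#' @export
generate_subjects <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_subjects
    cells <- rep(cell_levels(), length.out = n)
    true_wmh <- ifelse(cells %in% c("hw-no", "hw-o"), "high", "low")
    true_ob <- ifelse(cells %in% c("lw-o", "hw-o"), "obese", "non-obese")

    subject_id <- sprintf("sub%04d", seq_len(n))
    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    sex <- ifelse(stats::runif(n) < spec$male_fraction, "male", "female")

    cutoff <- ifelse(sex == "male", 0.90, 0.85)
    offset <- ifelse(true_ob == "obese",
                     spec$whr_params$obese_offset,
                     spec$whr_params$nonobese_offset)
    whr <- cutoff + offset + stats::rnorm(n, 0, spec$whr_params$sd)
    hip <- stats::rnorm(n, 103.21, 7.67)
    hip <- pmax(hip, 60)
    waist <- whr * hip
    bmi <- ifelse(true_ob == "obese",
                  stats::rnorm(n, 28.5, 4.0),
                  stats::rnorm(n, 25.5, 3.7))
    bmi <- pmax(bmi, 15)

    lp <- spec$wmh_lognormal_params
    meanlog <- ifelse(true_wmh == "high", lp$high$meanlog, lp$low$meanlog)
    sdlog <- ifelse(true_wmh == "high", lp$high$sdlog, lp$low$sdlog)
    total <- stats::rlnorm(n, meanlog, sdlog)
    pb <- spec$peri_fraction_beta
    frac <- stats::rbeta(n, pb$mean * pb$concentration,
                         (1 - pb$mean) * pb$concentration)
    peri <- frac * total
    deep <- total - peri

    list(
      subjects = data.frame(
        subject_id = subject_id, age = age, sex = sex,
        waist_cm = waist, hip_cm = hip, bmi = bmi,
        wmh_total_mm3 = total, wmh_deep_mm3 = deep, wmh_peri_mm3 = peri,
        stringsAsFactors = FALSE),
      labels = data.frame(
        subject_id = subject_id, true_wmh = true_wmh,
        true_obesity = true_ob, true_cell = cells,
        stringsAsFactors = FALSE))
  })
}

#' Construct a region time-series object
#'
#' @param subject_id Subject identifier.
#' @param data T x R numeric matrix (rows = timepoints, columns = regions).
#' @param region_ids Character labels for the R regions (default `r01`...).
#' @return An object of class `region_ts`.
#' @export
region_ts <- function(subject_id, data, region_ids = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 3L) stop("region_ts: need at least 3 timepoints")
  if (is.null(region_ids)) region_ids <- sprintf("r%02d", seq_len(ncol(data)))
  if (length(region_ids) != ncol(data))
    stop("region_ts: region_ids length must equal number of columns")
  colnames(data) <- region_ids
  structure(list(subject_id = subject_id, data = data,
                 region_ids = region_ids),
            class = "region_ts")
}

#' Generate per-subject region time series with implanted group structure
#'
#' Each subject's series is drawn from a zero-mean multivariate normal whose
#' correlation matrix is the spec's cell matrix: background correlation
#' everywhere except the effect node's edges to its neighbour set, which
#' carry the base correlation plus the obesity main-effect increment (obese
#' cells) plus the interaction increment (hw-o cell only). Optional age/sex
#' confound shifts are applied uniformly to the off-diagonal. Marginal SD is
#' `noise_sd`, so no column is constant.
#'
#' @param spec A validated [cohort_spec()].
#' @param labels Character vector of true cell labels (length n_subjects),
#'   or the `labels` data.frame from [generate_subjects()].
#' @param subjects Optional subject table; required when the confound
#'   parameters are nonzero (age and sex enter the correlation shift).
#' @return List of [region_ts()] objects, one per subject.
#' @export
generate_timeseries <- function(spec, labels, subjects = NULL) {
  validate_cohort_spec(spec)
  if (is.data.frame(labels)) {
    ids <- labels$subject_id
    labels <- labels$true_cell
  } else {
    ids <- sprintf("sub%04d", seq_along(labels))
  }
  if (length(labels) != spec$n_subjects)
    stop("generate_timeseries: labels length (", length(labels),
         ") must equal n_subjects (", spec$n_subjects, ")")
  confounded <- spec$confound_age_slope != 0 || spec$confound_sex_delta != 0
  if (confounded && is.null(subjects))
    stop("generate_timeseries: subjects table required when confound ",
         "parameters are nonzero")

  shifts <- rep(0, length(labels))
  if (confounded) {
    subjects <- subjects[match(ids, subjects$subject_id), ]
    shifts <- spec$confound_age_slope * (subjects$age - spec$age_mean) +
      spec$confound_sex_delta * as.numeric(subjects$sex == "male")
  }

  seed2 <- if (is.null(spec$seed)) NULL else spec$seed + 1L
  with_seed(seed2, {
    cache <- list()
    lapply(seq_along(labels), function(i) {
      cell <- labels[i]
      key <- if (shifts[i] == 0) cell else NA_character_
      A <- if (!is.na(key) && !is.null(cache[[key]])) {
        cache[[key]]
      } else {
        sigma <- cell_correlation_matrix(spec, cell, shift = shifts[i])
        ed <- eigen(sigma, symmetric = TRUE)
        if (min(ed$values) < -1e-8)
          stop("generate_timeseries: implied correlation matrix for ",
               "subject ", ids[i], " (cell ", cell,
               ") is not positive semi-definite")
        a <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
        if (!is.na(key)) cache[[key]] <<- a
        a
      }
      z <- matrix(stats::rnorm(spec$n_timepoints * spec$n_regions),
                  spec$n_timepoints, spec$n_regions)
      region_ts(ids[i], spec$noise_sd * (z %*% A))
    })
  })
}

#' Expand a region time series into a toy 4D image and parcellation
#'
#' Builds the simplest image a mean-extraction step can be validated on:
#' region j occupies `voxels_per_region` voxels, each voxel's series equals
#' the region signal plus independent Normal(0, noise_sd) noise, and the
#' integer label volume marks regions 1..R with 0 background. Averaging
#' voxels within a region therefore recovers the generating signal to
#' noise_sd / sqrt(voxels_per_region).
#'
#' @param n_regions Number of regions (must match `ncol(series$data)`).
#' @param voxels_per_region Voxels per region (>= 1).
#' @param series A [region_ts()] object.
#' @param seed Optional seed for the voxel noise.
#' @param noise_sd Voxel noise SD; 0 gives an exact round trip.
#' @return List with `image` (4D array, x = voxel-within-region,
#'   y = region, z = 1, t = time) and `labels` (3D integer array; one
#'   background voxel plane is appended along x).
#' @export
generate_toy_image <- function(n_regions, voxels_per_region, series,
                               seed = NULL, noise_sd = 0) {
  if (voxels_per_region < 1L)
    stop("generate_toy_image: voxels_per_region must be >= 1")
  if (ncol(series$data) != n_regions)
    stop("generate_toy_image: n_regions must match the series")
  Tn <- nrow(series$data)
  with_seed(seed, {
    img <- array(0, dim = c(voxels_per_region + 1L, n_regions, 1L, Tn))
    lab <- array(0L, dim = c(voxels_per_region + 1L, n_regions, 1L))
    for (j in seq_len(n_regions)) {
      sig <- series$data[, j]
      for (v in seq_len(voxels_per_region)) {
        img[v, j, 1L, ] <- sig +
          if (noise_sd > 0) stats::rnorm(Tn, 0, noise_sd) else 0
        lab[v, j, 1L] <- j
      }
    }
    list(image = img, labels = lab)
  })
}
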