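#' Pearson correlation matrix of a region time series
#'
#' @param ts A [region_ts()] (or bare T x R matrix), T >= 3, no constant
#'   column.
#' @return R x R symmetric correlation matrix with unit diagonal,
#'   dimnames = region ids.
#' @export
correlation_matrix <- function(ts) {
  data <- if (inherits(ts, "region_ts")) ts$data else as.matrix(ts)
  if (nrow(data) < 3L)
    stop("correlation_matrix: need at least 3 timepoints")
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(data)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("correlation_matrix: constant column for region(s) ",
         paste(bad, collapse = ", "))
  }
  r <- stats::cor(data)
  (r + t(r)) / 2  # enforce exact symmetry against rounding
}

#' Soft-threshold correlations toward scale-free topology
#'
#' Maps a correlation r in \[-1, 1\] to the edge weight ((r + 1) / 2)^beta.
#' The map is strictly increasing in r and sends -1 to 0 and 1 to 1; larger
#' beta suppresses weak edges more strongly. Default beta = 6, the
#' conventional scale-free index for weighted brain graphs.
#'
#' @param r Correlation(s) in \[-1, 1\] (vector or matrix).
#' @param beta Positive scale-free index (default 6).
#' @return Weights in \[0, 1\], same shape as `r`.
#' @examples
#' soft_threshold(0)      # 0.5^6 = 0.015625
#' soft_threshold(c(-1, 1))
#' @export
soft_threshold <- function(r, beta = 6) {
  if (beta <= 0) stop("soft_threshold: beta must be > 0")
  tol <- 1e-12
  if (any(r < -1 - tol | r > 1 + tol, na.rm = TRUE))
    stop("soft_threshold: correlations must lie in [-1, 1]")
  r <- pmin(pmax(r, -1), 1)
  ((r + 1) / 2)^beta
}

#' Fisher r-to-z transform of soft-thresholded weights
#'
#' Applies arctanh to a weight in \[0, 1\]; the pole at 1 is clipped at
#' 1 - 1e-7 so a perfect correlation yields a large finite z rather than
#' infinity.
#'
#' @param w Weight(s) in \[0, 1\].
#' @return z-values (>= 0 for weights >= 0), same shape as `w`.
#' @export
fisher_z <- function(w) {
  tol <- 1e-12
  if (any(w < -tol | w > 1 + tol, na.rm = TRUE))
    stop("fisher_z: weights must lie in [0, 1]")
  atanh(pmin(pmax(w, 0), 1 - 1e-7))
}

#' Build a subject's weighted connectivity graph
#'
#' Runs the full edge chain: Pearson correlation, soft-thresholding
#' ((r+1)/2)^beta, Fisher r-to-z. The diagonal (self-connections) is set to
#' 0 — arctanh of the self-correlation weight 1 would be infinite and
#' self-edges carry no information.
#'
#' @param ts A [region_ts()].
#' @param beta Scale-free index (default 6).
#' @return Object of class `connectivity_graph`: subject_id, `weights`
#'   (R x R symmetric, non-negative, zero diagonal), beta, region_ids.
#' @export
connectivity_graph <- function(ts, beta = 6) {
  r <- correlation_matrix(ts)
  w <- fisher_z(soft_threshold(r, beta = beta))
  diag(w) <- 0
  structure(list(subject_id = ts$subject_id, weights = w, beta = beta,
                 region_ids = ts$region_ids),
            class = "connectivity_graph")
}

#' Weighted degree centrality of a connectivity graph
#'
#' Degree centrality of node i is the sum of all edge weights incident to
#' i (row sum of the weight matrix, diagonal excluded).
#'
#' @param graph A `connectivity_graph`, or a symmetric weight matrix.
#' @return Named numeric vector of length R.
#' @export
degree_centrality <- function(graph) {
  w <- if (inherits(graph, "connectivity_graph")) graph$weights else graph
  if (!isSymmetric(unname(w), tol = 1e-10))
    stop("degree_centrality: weight matrix must be symmetric")
  w <- unname(w)
  diag(w) <- 0
  dc <- rowSums(w)
  names(dc) <- if (inherits(graph, "connectivity_graph"))
    graph$region_ids else rownames(graph)
  dc
}

#' Centrality table for a list of subjects
#'
#' @param ts_list List of [region_ts()] objects.
#' @param beta Scale-free index.
#' @return Subjects x regions matrix of raw degree centrality, rownames =
#'   subject ids, colnames = region ids.
#' @export
centrality_matrix <- function(ts_list, beta = 6) {
  rows <- lapply(ts_list, function(ts) degree_centrality(
    connectivity_graph(ts, beta = beta)))
  ids <- vapply(ts_list, function(ts) ts$subject_id, character(1))
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  mat
}

#' Residualise degree centrality on age and sex
#'
#' Per node, fits ordinary least squares of centrality on intercept + age +
#' sex across subjects (pooled over groups, so group effects are not
#' absorbed) and returns the residuals. Residuals are exactly orthogonal to
#' the covariate columns and have mean zero. A covariate with no variation
#' (e.g. a single-sex cohort) is dropped with a warning.
#'
#' @param centrality Subjects x nodes matrix of raw centrality.
#' @param age Numeric vector of ages (years), one per subject.
#' @param sex Character (`"male"`/`"female"`) or 0/1 numeric vector.
#' @return List with `adjusted` (same shape as `centrality`),
#'   `covariates_used` (character vector).
#' @export
adjust_covariates <- function(centrality, age, sex) {
  centrality <- as.matrix(centrality)
  n <- nrow(centrality)
  if (n < 4L) stop("adjust_covariates: need at least 4 subjects")
  if (length(age) != n || length(sex) != n)
    stop("adjust_covariates: covariate length must match subject count")
  if (any(is.na(age)) || any(is.na(sex)))
    stop("adjust_covariates: missing covariate values")
  sex_num <- if (is.numeric(sex)) sex else as.numeric(sex == "male")
  X <- cbind(intercept = 1, age = age, sex = sex_num)
  used <- c("age", "sex")
  if (stats::sd(age) == 0) {
    warning("adjust_covariates: age has no variation; dropped")
    X <- X[, colnames(X) != "age", drop = FALSE]
    used <- setdiff(used, "age")
  }
  if (stats::sd(sex_num) == 0) {
    warning("adjust_covariates: sex has no variation; dropped")
    X <- X[, colnames(X) != "sex", drop = FALSE]
    used <- setdiff(used, "sex")
  }
  qrX <- qr(X)
  resid <- qr.resid(qrX, centrality)
  dimnames(resid) <- dimnames(centrality)
  list(adjusted = resid, covariates_used = used)
}

#' Scale-free fit diagnostic
#'
#' R^2 of the log-log regression of the binned degree distribution, the
#' usual check that a soft-thresholded graph approximates scale-free
#' topology. Diagnostic only — beta is fixed at its conventional value, not
#' selected by this statistic.
#'
#' @param dc Degree centrality vector.
#' @param n_bins Number of bins (default 10).
#' @return R^2 in \[0, 1\] (NA if too few occupied bins).
#' @export
scale_free_fit <- function(dc, n_bins = 10) {
  brks <- seq(min(dc), max(dc), length.out = n_bins + 1)
  bin <- cut(dc, brks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  mid <- (brks[-1] + brks[-length(brks)]) / 2
  keep <- freq > 0 & mid > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[keep]) ~ log10(mid[keep]))
  summary(fit)$r.squared
}
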