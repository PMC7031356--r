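#' Classify obesity from the waist-hip ratio
#'
#' A subject is obese iff the waist-hip ratio strictly exceeds the
#' sex-specific cutoff: 0.90 for males, 0.85 for females. Ratios exactly at
#' the cutoff are non-obese (strict inequality).
#'
#' @param sex Character vector, `"male"` or `"female"`.
#' @param waist_cm,hip_cm Positive circumferences in cm.
#' @return Character vector, `"obese"` or `"non-obese"`.
#' @examples
#' classify_obesity("male", 99, 104)    # 0.952 > 0.90 -> obese
#' classify_obesity("male", 90, 100)    # exactly 0.90 -> non-obese
#' @export
classify_obesity <- function(sex, waist_cm, hip_cm) {
  if (any(is.na(sex)) || !all(sex %in% c("male", "female")))
    stop("classify_obesity: field 'sex' must be 'male' or 'female'")
  if (any(is.na(waist_cm)) || any(waist_cm <= 0))
    stop("classify_obesity: field 'waist_cm' must be positive")
  if (any(is.na(hip_cm)) || any(hip_cm <= 0))
    stop("classify_obesity: field 'hip_cm' must be positive")
  whr <- waist_cm / hip_cm
  cutoff <- ifelse(sex == "male", 0.90, 0.85)
  ifelse(whr > cutoff, "obese", "non-obese")
}

#' Median split of WMH volumes into low/high burden
#'
#' The cutoff is the cohort median (standard midpoint-of-order-statistics
#' for even n). A subject is high-burden iff its volume strictly exceeds
#' the median; ties at the median go to low, consistent with the strict
#' inequality used for the obesity cutoff.
#'
#' @param volumes Numeric vector of non-negative WMH volumes (mm^3).
#' @return Character vector, `"low"` or `"high"`.
#' @examples
#' split_by_median(c(1, 2, 3, 4))  # low low high high
#' split_by_median(c(5, 5, 5))     # all low
#' @export
split_by_median <- function(volumes) {
  if (length(volumes) < 2L)
    stop("split_by_median: need at least 2 subjects")
  if (any(is.na(volumes)) || any(volumes < 0))
    stop("split_by_median: volumes must be non-negative and non-missing")
  med <- stats::median(volumes)
  ifelse(volumes > med, "high", "low")
}

#' Assign factorial group membership per WMH criterion
#'
#' Crosses the median-split WMH-burden level with the WHR obesity level for
#' each requested criterion (total, deep, periventricular lesion volume),
#' yielding the four cells lw-no, lw-o, hw-no, hw-o. Empty cells are
#' flagged with a warning (downstream inference will reject them).
#'
#' @param subjects Subject table as produced by [generate_subjects()]
#'   (columns subject_id, sex, waist_cm, hip_cm, wmh_total_mm3,
#'   wmh_deep_mm3, wmh_peri_mm3).
#' @param criteria Subset of `c("total", "deep", "periventricular")`.
#' @return data.frame with one row per subject x criterion: subject_id,
#'   criterion, wmh_level, obesity_level, cell.
#' @export
assign_groups <- function(subjects,
                          criteria = c("total", "deep", "periventricular")) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  need <- c("subject_id", "sex", "waist_cm", "hip_cm",
            "wmh_total_mm3", "wmh_deep_mm3", "wmh_peri_mm3")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop("assign_groups: subject table lacks columns: ",
         paste(miss, collapse = ", "))
  obesity <- classify_obesity(subjects$sex, subjects$waist_cm,
                              subjects$hip_cm)
  vol_col <- c(total = "wmh_total_mm3", deep = "wmh_deep_mm3",
               periventricular = "wmh_peri_mm3")
  out <- do.call(rbind, lapply(criteria, function(cr) {
    wmh <- split_by_median(subjects[[vol_col[[cr]]]])
    cell <- paste0(ifelse(wmh == "high", "hw", "lw"), "-",
                   ifelse(obesity == "obese", "o", "no"))
    data.frame(subject_id = subjects$subject_id, criterion = cr,
               wmh_level = wmh, obesity_level = obesity, cell = cell,
               stringsAsFactors = FALSE)
  }))
  for (cr in criteria) {
    counts <- table(factor(out$cell[out$criterion == cr],
                           levels = cell_levels()))
    if (any(counts == 0))
      warning("assign_groups: empty cell(s) for criterion '", cr, "': ",
              paste(names(counts)[counts == 0], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Cell-count summary for a set of group assignments
#'
#' @param assignments Output of [assign_groups()].
#' @return data.frame with criterion, cell, n.
#' @export
cell_counts <- function(assignments) {
  out <- as.data.frame(table(
    criterion = assignments$criterion,
    cell = factor(assignments$cell, levels = cell_levels())),
    stringsAsFactors = FALSE)
  names(out)[3] <- "n"
  out[order(out$criterion, match(out$cell, cell_levels())), , drop = FALSE]
}
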