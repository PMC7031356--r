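#' Two-way factorial ANOVA of centrality on WMH burden and obesity
#'
#' Fits the 2x2 between-subjects model (WMH burden low/high, obesity
#' non-obese/obese, plus their interaction) and returns F and p for both
#' main effects and the interaction. Cells may be unbalanced; the default
#' sums of squares are Type III with sum-to-zero contrasts (each effect
#' tested adjusting for all others), with Type II available. Every effect
#' has 1 numerator df; the denominator df is N - 4.
#'
#' @param values Numeric vector (one node) or subjects x nodes matrix of
#'   adjusted centrality.
#' @param cells Character/factor of cell labels (`lw-no`, `lw-o`, `hw-no`,
#'   `hw-o`), one per subject; all four cells must be nonempty.
#' @param ss_type 3 (default) or 2.
#' @return data.frame with columns region_id, effect (`wmh`, `obesity`,
#'   `interaction`), F, df1, df2, p.
#' @examples
#' set.seed(1)
#' cells <- rep(cell_levels(), each = 3)
#' y <- rnorm(12) + ifelse(cells == "hw-o", 2, 0)
#' two_way_anova(y, cells)
#' @export
two_way_anova <- function(values, cells, ss_type = 3) {
  if (!ss_type %in% c(2, 3)) stop("two_way_anova: ss_type must be 2 or 3")
  Y <- if (is.matrix(values)) values else
    matrix(values, ncol = 1, dimnames = list(NULL, "value"))
  cells <- as.character(cells)
  if (length(cells) != nrow(Y))
    stop("two_way_anova: cells length must match subject count")
  bad <- setdiff(unique(cells), cell_levels())
  if (length(bad))
    stop("two_way_anova: unknown cell label(s) ", paste(bad, collapse = ", "))
  counts <- table(factor(cells, levels = cell_levels()))
  if (any(counts == 0))
    stop("two_way_anova: empty cell(s): ",
         paste(names(counts)[counts == 0], collapse = ", "))
  N <- nrow(Y)
  if (N < 8L) stop("two_way_anova: need at least 8 subjects")

  # sum-to-zero coding: low/non-obese = +1, high/obese = -1
  a <- ifelse(cells %in% c("lw-no", "lw-o"), 1, -1)     # wmh burden
  b <- ifelse(cells %in% c("lw-no", "hw-no"), 1, -1)    # obesity
  X <- cbind(`(Intercept)` = 1, wmh = a, obesity = b, interaction = a * b)
  df2 <- N - 4L

  qr_full <- qr(X)
  res_full <- qr.resid(qr_full, Y)
  rss_full <- colSums(res_full^2)
  mse <- rss_full / df2

  if (ss_type == 3) {
    xtx_inv <- chol2inv(qr.R(qr_full))
    coefs <- qr.coef(qr_full, Y)
    ssmat <- sapply(2:4, function(j) coefs[j, ]^2 / xtx_inv[j, j])
  } else {
    rss <- function(cols) colSums(qr.resid(qr(X[, cols, drop = FALSE]),
                                           Y)^2)
    ss_wmh <- rss(c(1, 3)) - rss(c(1, 2, 3))
    ss_ob <- rss(c(1, 2)) - rss(c(1, 2, 3))
    ss_int <- rss(c(1, 2, 3)) - rss_full
    ssmat <- cbind(ss_wmh, ss_ob, ss_int)
  }
  ssmat <- matrix(ssmat, ncol = 3)
  eps <- .Machine$double.eps * max(1, colSums(Y^2))
  zero_var <- mse <= eps
  Fmat <- ssmat / ifelse(mse > 0, mse, 1)
  if (any(zero_var)) {
    # perfect fit: a non-null effect SS gives p = 0, a null one p = 1
    warning("two_way_anova: zero residual variance for ",
            sum(zero_var), " node(s); p reported as 0 where the effect ",
            "sum of squares is nonzero")
    Fmat[zero_var, ] <- ifelse(ssmat[zero_var, , drop = FALSE] > eps,
                               Inf, 0)
  }
  pmat <- stats::pf(Fmat, 1, df2, lower.tail = FALSE)
  pmat[is.nan(pmat)] <- 1

  nodes <- colnames(Y)
  if (is.null(nodes)) nodes <- sprintf("node%02d", seq_len(ncol(Y)))
  effects <- c("wmh", "obesity", "interaction")
  out <- data.frame(
    region_id = rep(nodes, each = 3L),
    effect = rep(effects, times = length(nodes)),
    F = as.vector(t(Fmat)),
    df1 = 1L, df2 = df2,
    p = as.vector(t(pmat)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Standard step-up procedure with enforced monotonicity. The family is
#' chosen by the caller: all nodes for the per-node ANOVA p-values, or the
#' six pairwise comparisons within a node for the post-hoc tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @examples
#' fdr_correct(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdr_correct <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("fdr_correct: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Post-hoc pairwise t-tests between the four factorial cells
#'
#' Runs the six pairwise two-sample t-tests between cells, pooled-variance
#' Student's t by default (df = n1 + n2 - 2, matching the printed degrees
#' of freedom convention), with Welch's t available. T > 0 when the
#' first-listed group's mean is larger. q-values are BH-corrected across
#' the six pairs.
#'
#' @param values Numeric vector of adjusted centrality, one per subject.
#' @param cells Cell labels, one per subject.
#' @param var_equal Pooled-variance t (default TRUE); FALSE gives Welch.
#' @return data.frame: pair, n1, n2, T, df, p, q (one row per testable
#'   pair, canonical order).
#' @export
posthoc_pairwise <- function(values, cells, var_equal = TRUE) {
  cells <- as.character(cells)
  lv <- cell_levels()
  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    x <- values[cells == g1]; y <- values[cells == g2]
    if (length(x) < 2L || length(y) < 2L) {
      warning("posthoc_pairwise: pair ", g1, " vs. ", g2,
              " skipped (group with < 2 subjects)")
      return(NULL)
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    data.frame(pair = paste(g1, "vs.", g2),
               n1 = length(x), n2 = length(y),
               T = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(pair = character(0), n1 = integer(0),
                      n2 = integer(0), T = numeric(0), df = numeric(0),
                      p = numeric(0), q = numeric(0)))
  out$q <- fdr_correct(out$p)
  rownames(out) <- NULL
  out
}

#' Full node-level inference across WMH criteria
#'
#' For each requested criterion (total, deep, periventricular): runs the
#' per-node two-way ANOVA on adjusted centrality, BH-corrects p-values
#' across nodes (separately per effect), and runs post-hoc pairwise t-tests
#' for nodes whose interaction q-value falls below `alpha` (or all nodes
#' with `posthoc_all = TRUE`). Post-hoc q-values are corrected within each
#' node across its six pairs.
#'
#' @param assignments Group assignments from [assign_groups()].
#' @param centrality Subjects x nodes matrix of adjusted degree centrality,
#'   rownames = subject ids.
#' @param criteria Criteria to analyse (default all three).
#' @param alpha Significance level on the interaction q-value gating
#'   post-hoc tests.
#' @param ss_type Sums-of-squares type (3 or 2).
#' @param var_equal Pooled (TRUE) or Welch post-hoc t.
#' @param posthoc_all Run post-hoc tests at every node regardless of the
#'   interaction q-value.
#' @return List with `anova` (criterion, region_id, effect, F, df1, df2,
#'   p, q) and `posthoc` (criterion, region_id, pair, n1, n2, T, df, p, q),
#'   both ordered deterministically.
#' @export
run_analysis <- function(assignments, centrality,
                         criteria = c("total", "deep", "periventricular"),
                         alpha = 0.05, ss_type = 3, var_equal = TRUE,
                         posthoc_all = FALSE) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  centrality <- as.matrix(centrality)
  ids <- rownames(centrality)
  if (is.null(ids)) stop("run_analysis: centrality must have subject ids ",
                         "as rownames")
  anova_out <- list(); ph_out <- list()
  for (cr in criteria) {
    asg <- assignments[assignments$criterion == cr, ]
    missing_ids <- setdiff(ids, asg$subject_id)
    if (length(missing_ids))
      stop("run_analysis: no assignment for subject(s): ",
           paste(missing_ids, collapse = ", "))
    cells <- asg$cell[match(ids, asg$subject_id)]
    an <- two_way_anova(centrality, cells, ss_type = ss_type)
    an$q <- NA_real_
    for (eff in unique(an$effect))
      an$q[an$effect == eff] <- fdr_correct(an$p[an$effect == eff])
    an <- cbind(criterion = cr, an, stringsAsFactors = FALSE)
    anova_out[[cr]] <- an

    int_q <- an[an$effect == "interaction", ]
    hit_nodes <- if (posthoc_all) int_q$region_id else
      int_q$region_id[int_q$q < alpha]
    if (length(hit_nodes)) {
      ph <- do.call(rbind, lapply(hit_nodes, function(nd) {
        res <- posthoc_pairwise(centrality[, nd], cells,
                                var_equal = var_equal)
        if (!nrow(res)) return(NULL)
        cbind(criterion = cr, region_id = nd, res,
              stringsAsFactors = FALSE)
      }))
      ph_out[[cr]] <- ph
    }
  }
  anova <- do.call(rbind, anova_out)
  rownames(anova) <- NULL
  anova <- anova[order(anova$criterion, anova$region_id,
                       match(anova$effect, c("wmh", "obesity",
                                             "interaction"))), ]
  rownames(anova) <- NULL
  posthoc <- if (length(ph_out)) do.call(rbind, ph_out) else
    data.frame(criterion = character(0), region_id = character(0),
               pair = character(0), n1 = integer(0), n2 = integer(0),
               T = numeric(0), df = numeric(0), p = numeric(0),
               q = numeric(0))
  if (nrow(posthoc)) {
    posthoc <- posthoc[order(posthoc$criterion, posthoc$region_id,
                             posthoc$pair), ]
    rownames(posthoc) <- NULL
  }
  list(anova = anova, posthoc = posthoc)
}
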