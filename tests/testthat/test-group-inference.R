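test_that("Type III ANOVA matches the model-refit oracle, balanced and not", {
  set.seed(51)
  cases <- list(
    balanced = rep(cell_levels(), each = 6),
    unbalanced = rep(cell_levels(), times = c(9, 5, 7, 4)))
  for (cells in cases) {
    y <- rnorm(length(cells)) + 0.8 * (cells == "hw-o")
    got <- two_way_anova(y, cells)
    oracle <- bf_type3_anova(y, cells)
    expect_equal(got$F, unname(oracle[got$effect]), tolerance = 1e-10)
    expect_equal(got$df1, rep(1L, 3))
    expect_equal(got$df2, rep(length(cells) - 4L, 3))
    expect_equal(got$p, pf(got$F, 1, got$df2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("balanced designs: Type I, II and III agree", {
  set.seed(53)
  cells <- rep(cell_levels(), each = 5)
  y <- rnorm(20) + (cells %in% c("hw-no", "hw-o")) * 0.5
  a <- factor(ifelse(cells %in% c("lw-no", "lw-o"), "low", "high"))
  b <- factor(ifelse(cells %in% c("lw-no", "hw-no"), "no", "o"))
  type1 <- summary(aov(y ~ a * b))[[1]][["F value"]][1:3]
  got3 <- two_way_anova(y, cells)$F
  got2 <- two_way_anova(y, cells, ss_type = 2)$F
  expect_equal(got3, type1, tolerance = 1e-10)
  expect_equal(got2, type1, tolerance = 1e-10)
})

test_that("hand-decomposed 12-subject example with an hw-o-only shift", {
  # cell means {0, 0, 0, delta}: all three effects nonzero and equal SS in
  # the balanced case; verified against the refit oracle
  cells <- rep(cell_levels(), each = 3)
  y <- c(1, 2, 3, 2, 3, 1, 3, 1, 2, 7, 8, 9)  # delta = 6 on hw-o
  got <- two_way_anova(y, cells)
  oracle <- bf_type3_anova(y, cells)
  expect_equal(got$F, unname(oracle[got$effect]), tolerance = 1e-10)
  expect_true(all(got$F > 1))
  # in this balanced, single-cell-shift layout the three SS are identical
  expect_equal(got$F[1], got$F[2], tolerance = 1e-10)
  expect_equal(got$F[1], got$F[3], tolerance = 1e-10)
})

test_that("two-cell pooled t squares to the two-group ANOVA F", {
  set.seed(57)
  x <- rnorm(8); y <- rnorm(8) + 1
  tt <- bf_pooled_t(x, y)
  fit <- anova(lm(c(x, y) ~ rep(c("a", "b"), each = 8)))
  expect_equal(tt^2, fit[["F value"]][1], tolerance = 1e-10)
})

test_that("ANOVA rejects bad designs and handles degenerate variance", {
  y <- rnorm(12)
  expect_error(two_way_anova(y, rep(c("lw-no", "lw-o", "hw-no"), 4)),
               "empty cell.*hw-o")
  expect_error(two_way_anova(y[1:6], rep(cell_levels(), length.out = 6)),
               "at least 8")
  expect_error(two_way_anova(y, rep("nonsense", 12)), "unknown cell")
  # zero residual variance with a genuine effect: p = 0 with a warning
  cells <- rep(cell_levels(), each = 3)
  y_det <- ifelse(cells == "hw-o", 1, 0)
  expect_warning(res <- two_way_anova(y_det, cells), "zero residual")
  expect_equal(res$p[res$effect == "interaction"], 0)
  # all-constant input: no effect, p = 1
  expect_warning(res0 <- two_way_anova(rep(0, 12), cells), "zero residual")
  expect_equal(res0$p, rep(1, 3))
})

test_that("matrix ANOVA equals column-by-column ANOVA", {
  set.seed(59)
  cells <- rep(cell_levels(), times = c(5, 6, 4, 5))
  Y <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(NULL, paste0("r0", 1:4)))
  got <- two_way_anova(Y, cells)
  for (j in 1:4) {
    single <- two_way_anova(Y[, j], cells)
    expect_equal(got$F[got$region_id == colnames(Y)[j]], single$F,
                 tolerance = 1e-12)
  }
})

test_that("BH correction matches the step-up oracle and its invariants", {
  expect_equal(fdr_correct(0.01), 0.01)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(rep(0.05, 6)), rep(0.05, 6))
  expect_equal(fdr_correct(numeric(0)), numeric(0))
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(61)
  for (k in 1:25) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    q <- fdr_correct(p)
    expect_equal(q, bf_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    expect_equal(order(q[order(p)]), seq_along(p))  # ranking preserved
  }
})

test_that("post-hoc pairwise tests follow the pooled-t contract", {
  cells <- rep(cell_levels(), each = 3)
  vals <- rep(c(1, 2, 3), 4)
  same <- posthoc_pairwise(vals, cells)
  expect_equal(nrow(same), 6L)
  expect_equal(same$T, rep(0, 6))
  expect_equal(same$p, rep(1, 6))

  v2 <- c(1, 2, 3, 4, 5, 6, rep(0, 6))
  res <- posthoc_pairwise(v2, cells)
  row <- res[res$pair == "lw-no vs. lw-o", ]
  expect_equal(row$T, -3.674, tolerance = 5e-4)
  expect_equal(row$T, bf_pooled_t(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  expect_equal(row$df, 4)
  expect_equal(res$df, res$n1 + res$n2 - 2)
  # sign convention: first-listed group larger -> T > 0
  expect_gt(res[res$pair == "lw-o vs. hw-no", "T"], 0)

  # undersized group: its three pairs are skipped, each with a warning
  cells2 <- c(rep("lw-no", 3), "lw-o", rep("hw-no", 3), rep("hw-o", 3))
  w <- capture_warnings(res2 <- posthoc_pairwise(rnorm(10), cells2))
  expect_length(w, 3L)
  expect_true(all(grepl("skipped", w)))
  expect_equal(nrow(res2), 3L)
})

test_that("Welch option departs from pooled t under unequal variances", {
  set.seed(67)
  cells <- rep(cell_levels(), times = c(20, 5, 5, 5))
  v <- c(rnorm(20, 0, 4), rnorm(15, 0, 0.5))
  pooled <- posthoc_pairwise(v, cells, var_equal = TRUE)
  welch <- posthoc_pairwise(v, cells, var_equal = FALSE)
  expect_false(isTRUE(all.equal(pooled$df, welch$df)))
  expect_equal(pooled$df[1], 23)
})

test_that("run_analysis gates post-hoc on the interaction q-value", {
  set.seed(71)
  n <- 48
  cells <- rep(cell_levels(), each = n / 4)
  Y <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("r0", 1:6)))
  Y[cells == "hw-o", 3] <- Y[cells == "hw-o", 3] + 4  # big implant at r03
  ids <- sprintf("s%02d", 1:n)
  rownames(Y) <- ids
  asg <- data.frame(subject_id = ids, criterion = "total",
                    wmh_level = ifelse(grepl("hw", cells), "high", "low"),
                    obesity_level = ifelse(grepl("-o$", cells), "obese",
                                           "non-obese"),
                    cell = cells, stringsAsFactors = FALSE)
  res <- run_analysis(asg, Y, criteria = "total")
  an_int <- res$anova[res$anova$effect == "interaction", ]
  expect_equal(an_int$region_id[which.max(an_int$F)], "r03")
  expect_true(all(res$posthoc$region_id == "r03"))
  expect_equal(nrow(res$posthoc), 6L)
  # q >= p and within-family monotone
  expect_true(all(res$anova$q >= res$anova$p - 1e-15))
  # posthoc_all covers every node
  res_all <- run_analysis(asg, Y, criteria = "total", posthoc_all = TRUE)
  expect_equal(nrow(res_all$posthoc), 6L * 6L)
  # missing assignment is rejected with the subject named
  expect_error(run_analysis(asg[-1, ], Y, criteria = "total"), ids[1])
})

test_that("all-zero centrality yields no significance, empty post-hoc", {
  n <- 16
  cells <- rep(cell_levels(), each = 4)
  ids <- sprintf("s%02d", 1:n)
  Y <- matrix(0, n, 3, dimnames = list(ids, paste0("r0", 1:3)))
  asg <- data.frame(subject_id = ids, criterion = "total",
                    wmh_level = "low", obesity_level = "non-obese",
                    cell = cells, stringsAsFactors = FALSE)
  expect_warning(res <- run_analysis(asg, Y, criteria = "total"),
                 "zero residual")
  expect_true(all(res$anova$q == 1))
  expect_equal(nrow(res$posthoc), 0L)
})
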