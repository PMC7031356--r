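test_that("cohort_spec validates ranges and PSD structure", {
  expect_error(cohort_spec(n_subjects = 6), "n_subjects")
  expect_error(cohort_spec(n_timepoints = 2), "n_timepoints")
  expect_error(tiny_spec(noise_sd = 0), "noise_sd")
  expect_error(tiny_spec(base_correlation = 1), "base_correlation")
  # 0.75 to three mutually weakly-correlated neighbours is infeasible
  expect_error(
    cohort_spec(n_subjects = 8, n_regions = 10, n_timepoints = 50,
                base_correlation = 0.2, interaction_delta = 0.55),
    "positive semi-definite.*interaction_delta")
  # same edge value is feasible with a single neighbour
  expect_s3_class(
    cohort_spec(n_subjects = 8, n_regions = 10, n_timepoints = 50,
                base_correlation = 0.2, interaction_delta = 0.55,
                n_effect_neighbors = 1), "cohort_spec")
})

test_that("smallest balanced cohort: 8 records, 2 per cell, volumes > 0", {
  co <- generate_subjects(tiny_spec())
  expect_equal(nrow(co$subjects), 8L)
  expect_equal(as.integer(table(co$labels$true_cell)), rep(2L, 4))
  expect_true(all(co$subjects$wmh_total_mm3 > 0))
  expect_true(all(co$subjects$wmh_deep_mm3 >= 0))
  expect_true(all(co$subjects$waist_cm > 0 & co$subjects$hip_cm > 0))
})

test_that("subject invariants: volume additivity and WHR consistency", {
  co <- generate_subjects(cohort_spec(seed = 3))
  s <- co$subjects
  expect_equal(s$wmh_total_mm3, s$wmh_deep_mm3 + s$wmh_peri_mm3,
               tolerance = 1e-12)
  whr <- s$waist_cm / s$hip_cm
  expect_true(all(whr > 0.5 & whr < 1.3))
})

test_that("default demographics land near the target cohort", {
  # a single seed at a 2-SE band fails 5% of the time by construction, so
  # check 2-SE coverage of the age mean across 50 seeds instead
  zs <- vapply(seq(101, 150), function(s) {
    co <- generate_subjects(cohort_spec(seed = s))
    (mean(co$subjects$age) - 55.21) / (7.16 / sqrt(182))
  }, numeric(1))
  expect_gte(mean(abs(zs) < 2), 0.85)
  co <- generate_subjects(cohort_spec(seed = 7))
  s <- co$subjects
  expect_lt(abs(mean(s$age) - 55.21), 3 * 7.16 / sqrt(182))
  expect_lt(abs(mean(s$sex == "male") - 100 / 182), 0.12)
  # WHR marginal near 0.85 and right-skewed WMH volumes
  expect_lt(abs(mean(s$waist_cm / s$hip_cm) - 0.85), 0.03)
  expect_gt(mean(s$wmh_total_mm3), median(s$wmh_total_mm3))
})

test_that("seeded generation is bit-reproducible", {
  spec <- tiny_spec()
  a <- generate_subjects(spec); b <- generate_subjects(spec)
  expect_identical(a, b)
  ta <- generate_timeseries(spec, a$labels, a$subjects)
  tb <- generate_timeseries(spec, b$labels, b$subjects)
  expect_identical(ta, tb)
})

test_that("stratification recovers generating labels at default parameters", {
  # invariant checked as an average over 100 seeded cohorts
  ob <- wm <- numeric(100)
  for (s in seq_len(100)) {
    co <- generate_subjects(cohort_spec(seed = s))
    asg <- assign_groups(co$subjects, "total")
    m <- match(co$labels$subject_id, asg$subject_id)
    ob[s] <- mean((asg$obesity_level[m] == "obese") ==
                    (co$labels$true_obesity == "obese"))
    wm[s] <- mean((asg$wmh_level[m] == "high") ==
                    (co$labels$true_wmh == "high"))
  }
  expect_gte(mean(ob), 0.95)
  expect_gte(mean(wm), 0.90)
})

test_that("null series have equal effect-edge correlation across cells", {
  spec <- cohort_spec(n_subjects = 32, n_regions = 5, n_timepoints = 400,
                      seed = 5, obesity_main_delta = 0,
                      interaction_delta = 0)
  co <- generate_subjects(spec)
  ts <- generate_timeseries(spec, co$labels, co$subjects)
  nb <- effect_neighbors(spec)[1]
  r_by_cell <- tapply(
    vapply(ts, function(x) cor(x$data[, spec$effect_node],
                               x$data[, nb]), numeric(1)),
    co$labels$true_cell, mean)
  expect_lt(diff(range(r_by_cell)), 0.12)  # sampling error only
})

test_that("implanted interaction reaches its closed-form correlation", {
  # hw-o cell target r = 0.2 + 0.4 = 0.6, estimated over 200 series
  spec <- cohort_spec(n_subjects = 8, n_regions = 5, n_timepoints = 490,
                      seed = 1, base_correlation = 0.2,
                      interaction_delta = 0.4, n_effect_neighbors = 2)
  rs <- numeric(200)
  for (k in seq_len(200)) {
    sp <- cohort_spec(n_subjects = 8, n_regions = 5, n_timepoints = 490,
                      seed = 1000 + k, base_correlation = 0.2,
                      interaction_delta = 0.4, n_effect_neighbors = 2)
    ts <- generate_timeseries(sp, rep("hw-o", 8))
    rs[k] <- cor(ts[[1]]$data[, sp$effect_node],
                 ts[[1]]$data[, effect_neighbors(sp)[1]])
  }
  mc_se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs) - 0.6), 3 * mc_se + 0.6 * (1 - 0.6^2) / (2 * 490))
})

test_that("empirical covariance converges to the target in T", {
  spec0 <- function(T) cohort_spec(n_subjects = 8, n_regions = 5,
                                   n_timepoints = T, seed = 2)
  frob <- vapply(c(100, 1000, 10000), function(T) {
    sp <- spec0(T)
    ts <- generate_timeseries(sp, rep("lw-no", 8))
    target <- cell_correlation_matrix(sp, "lw-no")
    norm(cor(ts[[1]]$data) - target, "F")
  }, numeric(1))
  expect_true(all(diff(frob) < 0))
})

test_that("confounded correlations shift with age as specified", {
  spec <- cohort_spec(n_subjects = 8, n_regions = 5, n_timepoints = 50,
                      seed = 1, confound_age_slope = 0.004)
  co <- generate_subjects(spec)
  expect_error(generate_timeseries(spec, co$labels), "subjects table")
  ts <- generate_timeseries(spec, co$labels, co$subjects)
  expect_length(ts, 8L)
})

test_that("toy image round trip honours the noise model", {
  ts <- make_ts_fixture(T = 40, R = 3)
  # zero noise: exact recovery
  toy <- generate_toy_image(3, 4, ts, seed = 1, noise_sd = 0)
  got <- extract_mean_timeseries(toy$image, parcellation(toy$labels))
  expect_equal(unname(got$data), unname(ts$data), tolerance = 1e-12)
  # one voxel per region equals that voxel's series
  toy1 <- generate_toy_image(3, 1, ts, seed = 1, noise_sd = 0.5)
  got1 <- extract_mean_timeseries(toy1$image, parcellation(toy1$labels))
  expect_equal(unname(got1$data), t(unname(toy1$image[1, , 1, ])),
               tolerance = 1e-12)
  # noise_sd = 1 over 100 voxels: error SD ~ 0.1 (SE of the mean)
  ts2 <- make_ts_fixture(T = 400, R = 2)
  toy2 <- generate_toy_image(2, 100, ts2, seed = 9, noise_sd = 1)
  got2 <- extract_mean_timeseries(toy2$image, parcellation(toy2$labels))
  err_sd <- sd(got2$data - ts2$data)
  expect_lt(abs(err_sd - 0.1), 0.02)
})
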