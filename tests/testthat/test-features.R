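test_that("statistical features match hand-computed values", {
  const <- statistical_features(rep(2, 5))
  expect_equal(unname(const[c("mean", "median", "max", "rms")]), rep(2, 4))
  expect_equal(unname(const[c("sd", "iqr", "minmax_range")]), rep(0, 3))

  s <- statistical_features(1:5)
  expect_equal(unname(s["mean"]), 3)
  expect_equal(unname(s["median"]), 3)
  expect_equal(unname(s["max"]), 5)
  expect_equal(unname(s["minmax_range"]), 4)
  expect_equal(unname(s["rms"]), sqrt(11))
  expect_equal(unname(s["sd"]), sd(1:5))

  # all listed statistics are permutation invariant
  expect_equal(statistical_features(c(4, 1, 5, 2, 3)), s)
  expect_error(statistical_features(c(1, NA, 3)), "missing")
})

test_that("amplitude features: day-1 intensity and mean amplitude deviation", {
  a <- amplitude_features(c(4, 4, 4))
  expect_equal(unname(a), c(4, 0))
  expect_equal(unname(amplitude_features(c(0, 10))), c(0, 5))
  expect_equal(unname(amplitude_features(1:5)["mean_amplitude_deviation"]), 1.2)
})

test_that("cubic coefficients are recovered exactly on noiseless cubics", {
  for (W in 5:8) {
    x <- seq_len(W)
    y <- 2 * x^3 - x^2 + 3 * x + 1
    m <- morphological_features(y)
    expect_lt(abs(m[["coef_a"]] - 2), 1e-8)
    expect_lt(abs(m[["coef_b"]] + 1), 1e-8)
    expect_lt(abs(m[["coef_c"]] - 3), 1e-8)
  }
})

test_that("morphological features of a linear series are slope and zero curvature", {
  m <- morphological_features(c(1, 2, 3, 4, 5))
  expect_equal(m[["slope"]], 1)
  expect_equal(m[["mean_first_order_diff"]], 1)
  expect_equal(m[["mean_second_order_diff"]], 0)
  expect_lt(abs(m[["coef_a"]]), 1e-10)
  expect_lt(abs(m[["coef_b"]]), 1e-10)
  expect_error(morphological_features(c(1, 2, 3)), "at least 4")
})

test_that("OLS slope agrees with the normal-equation oracle on random windows", {
  set.seed(101)
  for (i in 1:200) {
    W <- sample(5:8, 1)
    y <- rnorm(W)
    x <- seq_len(W)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)  # independent normal equations
    expect_equal(morphological_features(y)[["slope"]], beta[2], tolerance = 1e-10)
  }
})

test_that("feature table has one row per eligible patient and documented columns", {
  cohort <- generate_cohort(cohort_spec(n_patients = 37, seed = 4))
  ft <- assemble_feature_table(cohort, W = 7)
  expect_equal(nrow(ft), 37)
  expect_equal(names(ft),
               c("patient_id",
                 "mean", "median", "sd", "iqr", "max", "minmax_range", "rms",
                 "intensity_day1", "mean_amplitude_deviation",
                 "slope", "coef_a", "coef_b", "coef_c",
                 "mean_first_order_diff", "mean_second_order_diff",
                 "BI", "FMS", "FAC", "MoCA", "label"))
  expect_equal(length(feature_names(ft)), 19)

  no_clin <- assemble_feature_table(cohort, W = 7, include_clinical = FALSE)
  expect_equal(length(feature_names(no_clin)), 15)

  # determinism
  expect_equal(ft, assemble_feature_table(cohort, W = 7))
  expect_error(assemble_feature_table(cohort, W = 9), "5, 6, 7, 8")
})

test_that("patients with missing days in the window are excluded and reported", {
  cohort <- generate_cohort(cohort_spec(n_patients = 10, seed = 6))
  victim <- cohort$patients$patient_id[1]
  cohort$daily$intensity[cohort$daily$patient_id == victim &
                           cohort$daily$rehab_day == 3] <- NA
  ft <- assemble_feature_table(cohort, W = 5)
  expect_equal(nrow(ft), 9)
  expect_equal(attr(ft, "exclusions"), victim)
})

test_that("min-max normalisation follows the published formula", {
  ft <- data.frame(patient_id = 1:3, f = c(2, 4, 6), label = "x")
  norm <- minmax_normalize(ft)
  expect_equal(norm$f, c(0, 0.5, 1))

  # an already-[0,1] feature is unchanged
  unit <- data.frame(patient_id = 1:3, f = c(0, 0.25, 1), label = "x")
  expect_equal(minmax_normalize(unit)$f, unit$f)

  # test rows transformed with training constants may leave [0,1]
  train_test <- data.frame(patient_id = 1:4, f = c(2, 4, 6, 8), label = "x")
  norm_tt <- minmax_normalize(train_test, fit_rows = 1:3)
  expect_equal(norm_tt$f[4], 1.5)

  # idempotent on the fit rows
  again <- minmax_normalize(norm)
  expect_equal(again$f, norm$f)

  # constant features are dropped with a warning
  cf <- data.frame(patient_id = 1:3, f = c(2, 4, 6), flat = 1, label = "x")
  expect_warning(dropped <- minmax_normalize(cf), "constant")
  expect_false("flat" %in% names(dropped))
})

test_that("every feature of a constant window is the constant or zero", {
  win <- rep(3, 7)
  all_f <- c(statistical_features(win), amplitude_features(win),
             morphological_features(win))
  keep_value <- c("mean", "median", "max", "rms", "intensity_day1")
  expect_true(all(abs(all_f[keep_value] - 3) < 1e-10))
  expect_true(all(abs(all_f[setdiff(names(all_f), keep_value)]) < 1e-10))
})
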