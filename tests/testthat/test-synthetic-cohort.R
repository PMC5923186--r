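test_that("generators are pure functions of the spec", {
  sp <- truth_spec(n_children = 60, seed = 7)
  expect_identical(generate_exposures(sp), generate_exposures(sp))
  expect_identical(generate_covariates(sp), generate_covariates(sp))
  s1 <- simulate_cohort(sp); s2 <- simulate_cohort(sp)
  expect_identical(s1$cohort, s2$cohort)
  # a different seed changes the draws
  expect_false(identical(generate_exposures(sp),
                         generate_exposures(truth_spec(n_children = 60,
                                                       seed = 8))))
})

test_that("degenerate exposure noise collapses to the mean", {
  sp <- truth_spec(n_children = 12, seasonal_amplitude = 0, ar1_rho = 0,
                   innovation_sd = 0, seed = 1)
  X <- generate_exposures(sp)
  expect_true(all(X == sp$exposure_mean))
  expect_identical(dim(X), c(12L, 40L))
})

test_that("exposures are non-negative and rectangular with labelled weeks", {
  sp <- truth_spec(n_children = 40, exposure_mean = 0.5,
                   seasonal_amplitude = 5, seed = 3)
  X <- generate_exposures(sp)
  expect_true(all(X >= 0))
  expect_identical(colnames(X)[c(1, 40)], c("pm25_wk01", "pm25_wk40"))
  expect_identical(rownames(X), sprintf("C%05d", 1:40))
})

test_that("categorical covariates follow the prevalence table", {
  sp <- truth_spec(n_children = 10000, seed = 2)
  cov <- generate_covariates(sp)
  expect_lt(abs(mean(cov$sex == "boy") - 0.521), 0.02)
  expect_lt(abs(mean(cov$race_ethnicity == "Hispanic") - 0.655), 0.02)
  expect_true(all(cov$gestational_age >= 37 & cov$gestational_age <= 41))
  # a degenerate block puts every row in that category
  pv <- default_prevalences()
  pv$sex <- c(girl = 1.0, boy = 0.0)
  cov2 <- generate_covariates(truth_spec(n_children = 50,
                                         covariate_prevalences = pv,
                                         seed = 2))
  expect_true(all(cov2$sex == "girl"))
})

test_that("invalid specs are rejected", {
  pv <- default_prevalences()
  pv$sex <- c(girl = 0.6, boy = 0.6)
  expect_error(truth_spec(covariate_prevalences = pv),
               class = "bdlimwin_invalid_spec")
  expect_error(truth_spec(T = 0), class = "bdlimwin_invalid_spec")
  expect_error(truth_spec(ar1_rho = 1), class = "bdlimwin_invalid_spec")
  expect_error(truth_spec(exposure_mean = NaN),
               class = "bdlimwin_invalid_spec")
  tl <- truth_spec()$true_lag_effects
  tl$fev1$boy <- numeric(10)
  expect_error(truth_spec(true_lag_effects = tl),
               class = "bdlimwin_invalid_spec")
})

test_that("misaligned ids and wrong-shaped truths are rejected", {
  sp <- truth_spec(n_children = 20, seed = 4)
  cov <- generate_covariates(sp)
  X <- generate_exposures(sp)
  Xbad <- X[rev(seq_len(nrow(X))), ]
  expect_error(generate_outcomes(cov, Xbad, sp),
               class = "bdlimwin_alignment_error")
  expect_error(generate_outcomes(cov, X[, 1:30], sp),
               class = "bdlimwin_shape_error")
})

test_that("an injected lag effect enters the outcome with coefficient one", {
  # two children identical except for +1 ug/m3 at week 37 differ in FEV1 by
  # exactly the injected per-week effect when all noise is switched off
  t0 <- 37L; d37 <- -0.004
  tl <- truth_spec()$true_lag_effects
  tl$fev1$boy <- lag_profile(40, t0, d37)
  sp <- truth_spec(n_children = 2, true_lag_effects = tl,
                   residual_sd = c(fev1 = 0, fvc = 0, fev1_fvc = 0,
                                   fef2575 = 0),
                   seed = 5)
  cov <- generate_covariates(sp)
  cov[2, setdiff(names(cov), "child_id")] <-
    cov[1, setdiff(names(cov), "child_id")]
  cov$sex <- factor(c("boy", "boy"), levels = c("girl", "boy"))
  X <- generate_exposures(sp)
  X[2, ] <- X[1, ]
  X[2, t0] <- X[1, t0] + 1
  out <- generate_outcomes(cov, X, sp)
  expect_equal(out$fev1[2] - out$fev1[1], d37, tolerance = 1e-12)
  # and with no noise and a null truth, outcomes are deterministic
  sp0 <- truth_spec(n_children = 2,
                    residual_sd = c(fev1 = 0, fvc = 0, fev1_fvc = 0,
                                    fef2575 = 0),
                    seed = 5)
  o1 <- generate_outcomes(cov, X, sp0)
  o2 <- generate_outcomes(cov, X, sp0)
  expect_identical(o1$fvc, o2$fvc)
  expect_equal(o1$fvc[1], o1$fvc[2], tolerance = 1e-12)
})

test_that("null truth shows no exposure-outcome association", {
  hits <- 0L
  for (s in 1:20) {
    sp <- truth_spec(n_children = 300, seed = 100 + s)
    sim <- simulate_cohort(sp)
    pm <- rowMeans(sim$exposures)
    fit <- summary(stats::lm(sim$cohort$fev1 ~ pm))$coefficients
    if (abs(fit["pm", 1]) < 3 * fit["pm", 2]) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("generated cohorts satisfy their structural invariants", {
  for (s in c(11, 12, 13)) {
    sim <- simulate_cohort(truth_spec(n_children = 400, seed = s))
    co <- sim$cohort
    expect_true(all(co$fev1 <= co$fvc))
    expect_equal(co$fev1_fvc, co$fev1 / co$fvc, tolerance = 1e-9)
    sites <- as.matrix(co[, grep("^gstp1_s", names(co))])
    expect_identical(ncol(sites), 17L)
    expect_true(all(sites >= 0 & sites <= 100))
    expect_true(all(is.finite(sim$exposures)) && all(sim$exposures >= 0))
  }
})

test_that("raw spirometry marginals match the cohort descriptives", {
  sim <- simulate_cohort(truth_spec(n_children = 4000, seed = 21))
  expect_lt(abs(mean(sim$cohort$fev1) - 1.44), 0.05)
  expect_lt(abs(mean(sim$cohort$fvc) - 1.58), 0.06)
  expect_lt(abs(mean(sim$cohort$fef2575) - 1.87), 0.06)
  expect_lt(abs(stats::sd(sim$cohort$fef2575) - 0.46), 0.06)
})

test_that("lag-truth calibration converts z-scale effects to raw scale", {
  sp <- truth_spec(n_children = 500, seed = 1)
  d <- calibrate_lag_truth(sp, "fev1", 35:40, -0.10)
  expect_identical(length(as.numeric(d)), 40L)
  expect_equal(sum(d), -0.10 * attr(d, "residual_sd"), tolerance = 1e-12)
  expect_true(all(d[1:34] == 0))
  # pure function: same spec gives the same calibration
  expect_equal(as.numeric(d),
               as.numeric(calibrate_lag_truth(sp, "fev1", 35:40, -0.10)))
})
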