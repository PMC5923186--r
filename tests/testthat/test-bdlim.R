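test_that("degenerate designs are rejected with informative errors", {
  d <- make_analysis_cohort(60, seed = 41)
  Xconst <- matrix(5, 60, 40)
  expect_error(fit_bdlim(d$scores$z_fev1, Xconst, d$Z, spec = quick_spec()),
               class = "bdlimwin_unidentifiable_exposure")
  Zbad <- cbind(d$Z, dup = d$Z[, "maternal_age"])
  expect_error(fit_bdlim(d$scores$z_fev1, d$exposures, Zbad,
                         spec = quick_spec()),
               class = "bdlimwin_collinearity_error")
  expect_error(fit_bdlim(d$scores$z_fev1, d$exposures, d$Z,
                         spec = quick_spec(pattern = "bw")),
               class = "bdlimwin_invalid_spec")
  expect_error(bdlim_spec(iter = 100, burnin = 200),
               class = "bdlimwin_invalid_spec")
})

test_that("the sampler is reproducible given the seed", {
  d <- make_analysis_cohort(80, seed = 42)
  f1 <- suppressWarnings(fit_bdlim(d$scores$z_fev1, d$exposures, d$Z,
                                   d$sex, quick_spec("bw", seed = 5)))
  f2 <- suppressWarnings(fit_bdlim(d$scores$z_fev1, d$exposures, d$Z,
                                   d$sex, quick_spec("bw", seed = 5)))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$dic$dic, f2$dic$dic)
})

test_that("retained weight draws are unit-norm with non-negative sum", {
  d <- make_analysis_cohort(100, seed = 43)
  f <- suppressWarnings(fit_bdlim(d$scores$z_fev1, d$exposures, d$Z,
                                  d$sex, quick_spec("bw", seed = 2)))
  for (g in f$groups) {
    W <- f$draws$w[[g]]
    expect_lt(max(abs(rowSums(W^2) - 1)), 1e-10)
    expect_true(all(rowSums(W) >= 0))
  }
})

test_that("pattern n ignores the grouping entirely", {
  d <- make_analysis_cohort(90, seed = 44)
  f1 <- suppressWarnings(fit_bdlim(d$scores$z_fev1, d$exposures, d$Z,
                                   d$sex, quick_spec("n", seed = 3)))
  perm <- sample(d$sex)
  f2 <- suppressWarnings(fit_bdlim(d$scores$z_fev1, d$exposures, d$Z,
                                   perm, quick_spec("n", seed = 3)))
  expect_identical(f1$draws$beta$girl, f2$draws$beta$girl)
  expect_identical(f1$draws$w$boy, f2$draws$w$boy)
  # shared-pattern draws are the same object for both groups
  expect_identical(f1$draws$w$girl, f1$draws$w$boy)
  expect_identical(f1$draws$beta$girl, f1$draws$beta$boy)
})

test_that("fixed-weight posterior matches the conjugate closed form and OLS", {
  d <- make_analysis_cohort(150, seed = 45)
  w <- rep(1 / sqrt(40), 40)
  f <- fit_bdlim(d$scores$z_fev1, d$exposures, d$Z,
                 spec = bdlim_spec(iter = 21000, burnin = 1000, thin = 1,
                                   seed = 6),
                 fixed_weights = w)
  Xc <- sweep(d$exposures, 2, colMeans(d$exposures))
  D <- cbind(d$Z, drop(Xc %*% w))
  cl <- nig_closed_form(D, d$scores$z_fev1)
  beta <- f$draws$beta$all
  mcse <- stats::sd(beta) / sqrt(length(beta))
  expect_lt(abs(mean(beta) - cl$mean[length(cl$mean)]), 3 * mcse)
  ols <- normal_eq_coefs(D, d$scores$z_fev1)
  expect_lt(abs(mean(beta) - ols[length(ols)]), 3 * mcse)
  # gamma posterior means agree with the closed form too
  expect_lt(max(abs(colMeans(f$draws$gamma) - cl$mean[1:ncol(d$Z)])), 5e-3)
})

test_that("rescaling the exposures inversely rescales the effect", {
  tl <- truth_spec()$true_lag_effects
  tl$fev1$boy <- lag_profile(40, 25:40, -0.08)
  tl$fev1$girl <- tl$fev1$boy
  d <- make_analysis_cohort(300, seed = 46, true_lag_effects = tl)
  f1 <- suppressWarnings(fit_bdlim(d$scores$z_fev1, d$exposures, d$Z,
                                   spec = quick_spec("n", seed = 7,
                                                     iter = 3000,
                                                     burnin = 1000)))
  f2 <- suppressWarnings(fit_bdlim(d$scores$z_fev1, 2 * d$exposures, d$Z,
                                   spec = quick_spec("n", seed = 7,
                                                     iter = 3000,
                                                     burnin = 1000)))
  b1 <- mean(f1$draws$beta$all); b2 <- mean(f2$draws$beta$all)
  expect_lt(abs(b2 - b1 / 2), 0.2 * abs(b1 / 2) + 2e-3)
  # weights are scale-free
  expect_lt(max(abs(colMeans(f1$draws$w$all) - colMeans(f2$draws$w$all))),
            0.12)
})

test_that("a single contiguous window is recovered from strong signals", {
  # smooth single-bump truth over weeks 18-30; the basis dimension is set
  # fine enough to resolve an 11-week feature (about one knot per 5 weeks),
  # as the DIC knot search would choose for so strong a signal
  wks <- 18:30
  bump <- sin(seq(0, pi, length.out = length(wks)))^2
  truth <- numeric(40); truth[wks] <- -0.15 * bump / sum(bump)
  cors <- vapply(1:10, function(s) {
    tl <- truth_spec()$true_lag_effects
    tl$fev1$boy <- truth
    tl$fev1$girl <- truth
    d <- make_analysis_cohort(800, seed = 300 + s, true_lag_effects = tl)
    f <- suppressWarnings(fit_bdlim(d$scores$z_fev1, d$exposures, d$Z,
                                    spec = quick_spec("n", seed = s, df = 9,
                                                      iter = 4000,
                                                      burnin = 1500)))
    est <- colMeans(lag_effect_draws(f, "all"))
    stats::cor(est, truth)
  }, numeric(1))
  expect_gt(median(cors), 0.9)
})

test_that("non-convergent chains are flagged rather than silently accepted", {
  d <- make_analysis_cohort(60, seed = 47)
  expect_warning(
    fit_bdlim(d$scores$z_fev1, d$exposures, d$Z, d$sex,
              bdlim_spec(pattern = "bw", iter = 1200, burnin = 200,
                         thin = 5, seed = 8)),
    regexp = "non-convergent")
})
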