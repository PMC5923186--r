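test_that("daily-to-weekly aggregation averages calendar weeks", {
  expect_equal(daily_to_weekly(rep(10, 280), 40),
               structure(rep(10, 40), missing_weeks = integer(0)))
  expect_equal(as.numeric(daily_to_weekly(1:14, 2)), c(4, 11))
})

test_that("a trailing partial week is averaged over its available days", {
  set.seed(42)
  daily <- stats::runif(283, 5, 15)
  wk <- daily_to_weekly(daily, 41)
  # brute-force slicing oracle
  oracle <- vapply(1:41, function(t) {
    idx <- (7 * (t - 1) + 1):min(7 * t, 283)
    mean(daily[idx])
  }, numeric(1))
  expect_equal(as.numeric(wk), oracle, tolerance = 1e-12)
  expect_equal(wk[41], mean(daily[281:283]))
  # weeks entirely beyond the series are flagged missing
  wk2 <- daily_to_weekly(daily[1:270], 41)
  expect_identical(attr(wk2, "missing_weeks"), 40:41)
})

test_that("daily aggregation rejects empty or negative series", {
  expect_error(daily_to_weekly(numeric(0)), class = "bdlimwin_empty_input")
  expect_error(daily_to_weekly(c(1, -2, 3)),
               class = "bdlimwin_validation_error")
})

test_that("long daily tables reshape to the weekly wide matrix", {
  long <- data.frame(
    child_id = rep(c("a", "b"), each = 14),
    gestational_day = rep(1:14, 2),
    pm25 = c(1:14, rep(7, 14))
  )
  m <- weekly_exposure_matrix(long, T = 2)
  expect_equal(unname(m), rbind(c(4, 11), c(7, 7)))
  expect_identical(colnames(m), c("pm25_wk01", "pm25_wk02"))
  expect_error(weekly_exposure_matrix(long[, 1:2], T = 2),
               class = "bdlimwin_schema_error")
})

test_that("z-scores have mean zero, unit SD, and match the least-squares oracle", {
  sim <- simulate_cohort(truth_spec(n_children = 200, seed = 31))
  zp <- compute_lung_zscores(sim$cohort)
  for (col in names(zp$scores)) {
    expect_lt(abs(mean(zp$scores[[col]])), 1e-8)
    expect_lt(abs(stats::sd(zp$scores[[col]]) - 1), 1e-8)
  }
  # independently coded least-squares oracle
  mm <- stats::model.matrix(~ child_age + sex + height + race_ethnicity,
                            data = sim$cohort)
  or <- normal_eq_summary(mm, sim$cohort$fev1)
  expect_equal(zp$scores$z_fev1,
               unname(or$residuals / stats::sd(or$residuals)),
               tolerance = 1e-8)
  expect_equal(unname(zp$coefficients$fev1), unname(or$coef),
               tolerance = 1e-8)
})

test_that("z-score residuals are orthogonal to every standardization column", {
  sim <- simulate_cohort(truth_spec(n_children = 150, seed = 32))
  zp <- compute_lung_zscores(sim$cohort)
  mm <- stats::model.matrix(~ child_age + sex + height + race_ethnicity,
                            data = sim$cohort)
  for (col in names(zp$scores)) {
    expect_lt(max(abs(crossprod(mm, zp$scores[[col]]))) / nrow(mm), 1e-8)
  }
})

test_that("re-standardizing a z-score with an intercept-only design is a no-op", {
  sim <- simulate_cohort(truth_spec(n_children = 120, seed = 33))
  zp <- compute_lung_zscores(sim$cohort)
  d2 <- data.frame(fev1 = zp$scores$z_fev1)
  zp2 <- compute_lung_zscores(d2, outcomes = "fev1",
                              covariates = character(0))
  expect_equal(zp2$scores$z_fev1, zp$scores$z_fev1, tolerance = 1e-10)
})

test_that("degenerate and collinear standardization designs are rejected", {
  sim <- simulate_cohort(truth_spec(n_children = 80, seed = 34))
  d <- sim$cohort
  d$fev1 <- 1 + 2 * d$child_age + 0.01 * d$height   # exact linear function
  expect_error(compute_lung_zscores(d, outcomes = "fev1"),
               class = "bdlimwin_degenerate_outcome")
  d2 <- sim$cohort
  d2$height2 <- d2$height
  expect_error(
    compute_lung_zscores(d2, outcomes = "fev1",
                         covariates = c("height", "height2")),
    class = "bdlimwin_collinearity_error")
  expect_error(compute_lung_zscores(d2, outcomes = "nope"),
               class = "bdlimwin_schema_error")
  d3 <- sim$cohort; d3$height[1] <- NA
  expect_error(compute_lung_zscores(d3),
               class = "bdlimwin_validation_error")
})

test_that("percent methylation is the methylated fraction of total reads", {
  expect_equal(percent_methylation(1, 3), 25)
  expect_equal(percent_methylation(5, 0), 100)
  set.seed(9)
  m <- stats::rpois(17, 20); u <- stats::rpois(17, 400) + 1
  expect_equal(percent_methylation(m, u), 100 * m / (m + u),
               tolerance = 1e-12)
  expect_error(percent_methylation(0, 0), class = "bdlimwin_undefined_site")
  expect_error(percent_methylation(-1, 2),
               class = "bdlimwin_validation_error")
})

test_that("the 17-site summary averages non-missing sites", {
  expect_equal(summarize_gstp1(rep(2, 17)),
               list(mean_5mC = 2, n_missing = 0))
  v <- c(1, 2, 3, rep(NA, 14))
  expect_equal(summarize_gstp1(v), list(mean_5mC = 2, n_missing = 14))
  expect_error(summarize_gstp1(rep(NA_real_, 17)),
               class = "bdlimwin_missing_data")
  set.seed(10)
  m <- matrix(stats::runif(5 * 17, 0, 10), 5, 17)
  s <- summarize_gstp1(m)
  expect_equal(s$mean_5mC, rowMeans(m), tolerance = 1e-12)
})

test_that("top-quartile dichotomization follows the type-7 quantile rule", {
  s <- dichotomize_top_quartile(1:8)
  expect_equal(s$threshold, 6.25)
  expect_identical(which(s$high_methylation), 7:8)
  expect_identical(c(s$n_high, s$n_low), c(2L, 6L))
  expect_error(dichotomize_top_quartile(rep(3, 10)),
               class = "bdlimwin_degenerate_distribution")
  expect_error(dichotomize_top_quartile(c(1, 2, 3)),
               class = "bdlimwin_validation_error")
})

test_that("the high-methylation fraction is a quarter on continuous data", {
  for (s in 1:5) {
    set.seed(200 + s)
    v <- stats::rlnorm(101, 0.8, 0.5)
    d <- dichotomize_top_quartile(v)
    expect_lte(abs(d$n_high - 0.25 * length(v)), 1)
    expect_true(all((v >= d$threshold) == d$high_methylation))
  }
})
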