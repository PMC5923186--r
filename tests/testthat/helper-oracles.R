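# Independent oracles and shared fixture builders.

# least squares via the normal equations (independent of lm/lm.fit)
normal_eq_coefs <- function(D, y) {
  drop(solve(crossprod(D), crossprod(D, y)))
}

normal_eq_summary <- function(D, y) {
  co <- normal_eq_coefs(D, y)
  r <- y - drop(D %*% co)
  df <- length(y) - ncol(D)
  s2 <- sum(r^2) / df
  se <- sqrt(diag(solve(crossprod(D))) * s2)
  p <- 2 * stats::pt(abs(co / se), df, lower.tail = FALSE)
  list(coef = co, se = se, p = p, residuals = r)
}

# closed-form normal-inverse-gamma linear model:
# theta | s2 ~ N(0, c2 s2 I), s2 ~ IG(a, b)
nig_closed_form <- function(D, y, c2 = 100, a = 0.01, b = 0.01) {
  n <- length(y)
  M <- crossprod(D); diag(M) <- diag(M) + 1 / c2
  Mi <- chol2inv(chol(M))
  Dty <- crossprod(D, y)
  m <- drop(Mi %*% Dty)
  astar <- a + n / 2
  bstar <- b + 0.5 * (sum(y^2) - sum(m * Dty))
  rssm <- sum((y - D %*% m)^2)
  dbar <- n * log(2 * pi) + n * (log(bstar) - digamma(astar)) +
    rssm * astar / bstar + sum(diag(crossprod(D) %*% Mi))
  s2hat <- bstar / (astar - 1)
  dhat <- n * log(2 * pi * s2hat) + rssm / s2hat
  list(mean = m, a = astar, b = bstar,
       dbar = dbar, dhat = dhat, pd = dbar - dhat, dic = 2 * dbar - dhat)
}

# type-7 sample quantile, coded independently of stats::quantile
quantile_type7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

# cohort with balanced sexes, z-scores and the maternal-covariate design
make_analysis_cohort <- function(n, seed, true_lag_effects = NULL,
                                 balanced_sex = TRUE) {
  sp <- truth_spec(n_children = n, true_lag_effects = true_lag_effects,
                   seed = seed)
  cov <- generate_covariates(sp)
  if (balanced_sex) {
    cov$sex <- factor(rep(c("girl", "boy"), length.out = n),
                      levels = c("girl", "boy"))
  }
  X <- generate_exposures(sp)
  cohort <- generate_outcomes(cov, X, sp)
  zp <- compute_lung_zscores(cohort)
  list(cohort = cohort, exposures = X, scores = zp$scores,
       Z = stats::model.matrix(~ maternal_age + maternal_education,
                               data = cohort),
       sex = cohort$sex, spec = sp)
}

# small-but-valid MCMC settings for unit tests (200 retained draws)
quick_spec <- function(pattern = "n", seed = 1, df = 5,
                       iter = 1500, burnin = 500, thin = 5) {
  bdlim_spec(pattern = pattern, df = df, iter = iter, burnin = burnin,
             thin = thin, seed = seed)
}
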