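#' Generate weekly gestational PM2.5 exposures
#'
#' Simulates an n x T matrix of weekly mean PM2.5 (ug/m3) as
#' `exposure_mean` + an annual sinusoid with a random conception phase per
#' subject + stationary AR(1) noise, truncated at zero. The process is a
#' stand-in for ambient exposure predictions; only its marginal summaries are
#' calibrated (pregnancy-average median 10.9, IQR about 10.2-11.7 ug/m3
#' under the defaults), while the seasonal + AR(1) structure supplies the
#' week-to-week autocorrelation that makes window estimation non-trivial.
#'
#' @param spec A [truth_spec()].
#' @return Matrix with rownames = child ids and columns `pm25_wk01`..`pm25_wkT`.
#' @export
generate_exposures <- function(spec) {
  stopifnot(inherits(spec, "truth_spec"))
  n <- spec$n_children; T <- spec$T
  set.seed(sub_seed(spec$seed, 1L))
  phase <- stats::runif(n, 0, 52)
  season <- spec$seasonal_amplitude *
    sin(2 * pi * outer(phase, seq_len(T), `+`) / 52)
  innov <- spec$innovation_sd
  rho <- spec$ar1_rho
  ar <- matrix(0, n, T)
  prev <- stats::rnorm(n, 0, if (innov > 0) innov / sqrt(1 - rho^2) else 0)
  for (t in seq_len(T)) {
    prev <- rho * prev + stats::rnorm(n, 0, innov)
    ar[, t] <- prev
  }
  X <- pmax(spec$exposure_mean + season + ar, 0)
  dimnames(X) <- list(child_ids(n), sprintf("pm25_wk%02d", seq_len(T)))
  X
}

child_ids <- function(n) sprintf("C%05d", seq_len(n))

#' Generate cohort covariates
#'
#' Draws the covariate table: child sex, race/ethnicity, maternal education,
#' pre/postnatal smoking, asthma (categoricals from the spec prevalences);
#' child age at spirometry ~ Normal(6.9, 0.8) years, maternal age at
#' enrollment ~ Normal(27.2, 5.7) years, height linear in age (122 cm at the
#' mean age, slope 6 cm/yr, SD 5 cm), gestational age uniform on completed
#' weeks 37..41 (the full-term analysis sample).
#'
#' @param spec A [truth_spec()].
#' @return A data.frame with one row per child (covariate columns only).
#' @export
generate_covariates <- function(spec) {
  stopifnot(inherits(spec, "truth_spec"))
  n <- spec$n_children
  pv <- spec$covariate_prevalences
  set.seed(sub_seed(spec$seed, 2L))
  draw_cat <- function(p) {
    factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
  }
  child_age <- stats::rnorm(n, 6.9, 0.8)
  height <- 122 + 6 * (child_age - 6.9) + stats::rnorm(n, 0, 5)
  data.frame(
    child_id = child_ids(n),
    sex = draw_cat(pv$sex),
    race_ethnicity = draw_cat(pv$race_ethnicity),
    maternal_education = draw_cat(pv$maternal_education),
    smoking = draw_cat(pv$smoking),
    asthma = draw_cat(pv$asthma) == "yes",
    child_age = child_age,
    height = height,
    maternal_age = stats::rnorm(n, 27.2, 5.7),
    gestational_age = sample(37:41, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# standardized age/sex/height/race component; an exact linear function of the
# z-score adjustment covariates, so regression standardization removes it
spiro_cov_component <- function(cov) {
  age_s <- (cov$child_age - 6.9) / 0.8
  height_s <- (cov$height - 122 - 6 * (cov$child_age - 6.9)) / 5
  boy <- as.numeric(cov$sex == "boy")
  race_shift <- c(Black = -0.08, Hispanic = 0, White_Other = 0.08)
  rs <- race_shift[as.character(cov$race_ethnicity)]
  (0.50 * age_s + 0.35 * height_s + 0.10 * (boy - 0.521) + rs) / 0.615
}

maternal_component <- function(cov, cc) {
  mat_s <- (cov$maternal_age - 27.2) / 5.7
  le12 <- as.numeric(cov$maternal_education == "le12y")
  cc$maternal_age * mat_s + cc$maternal_education * (le12 - 0.667)
}

#' Fill in spirometry and methylation outcomes
#'
#' Adds raw spirometry (FEV1, FVC, FEV1/FVC, FEF25-75) and a 17-site GSTP1
#' percent-methylation panel to a covariate table, using the linear outcome
#' model `raw = intercept + covariate effects + sum_t delta*_{sex,t} x_t +
#' noise`. True lag effects enter the raw outcome with coefficient exactly 1.
#' FEV1 is built as (latent ratio) x FVC with its own lag term and noise, so
#' `fev1 <= fvc` and `fev1_fvc == fev1/fvc` hold by construction. Child-level
#' methylation is lognormal (right-skewed; median 2.26 under the defaults)
#' plus its lag term, clipped to \[0, 100\]; the 17 site values are scaled so
#' their mean reproduces the child-level value exactly.
#'
#' @param covariates Covariate table from [generate_covariates()].
#' @param exposures Exposure matrix from [generate_exposures()]; rownames
#'   must match `covariates$child_id` in order.
#' @param spec The same [truth_spec()] used to generate the inputs.
#' @return The covariate data.frame with outcome columns appended:
#'   `fev1`, `fvc`, `fev1_fvc`, `fef2575`, and `gstp1_s01`..`gstp1_s17`.
#' @export
generate_outcomes <- function(covariates, exposures, spec) {
  stopifnot(inherits(spec, "truth_spec"))
  n <- nrow(covariates); T <- spec$T
  if (!identical(rownames(exposures), covariates$child_id)) {
    stop_bdlimwin("bdlimwin_alignment_error",
                  "exposure rownames do not match covariate child ids")
  }
  if (ncol(exposures) != T) {
    stop_bdlimwin("bdlimwin_shape_error",
                  "exposure matrix column count differs from spec T")
  }
  for (o in names(spec$true_lag_effects)) {
    for (g in c("girl", "boy")) {
      if (length(spec$true_lag_effects[[o]][[g]]) != T) {
        stop_bdlimwin("bdlimwin_shape_error",
                      "true lag effect vector length differs from T")
      }
    }
  }
  cc <- spec$covariate_coefficients
  rsd <- spec$residual_sd
  set.seed(sub_seed(spec$seed, 3L))

  cs <- spiro_cov_component(covariates)
  mat <- maternal_component(covariates, cc)
  boy <- covariates$sex == "boy"

  lag_term <- function(outcome) {
    d <- spec$true_lag_effects[[outcome]]
    drop(exposures %*% d$girl) * (!boy) + drop(exposures %*% d$boy) * boy
  }

  load <- cc$cov_loading
  fvc <- 1.58 + 0.29 * (load * cs + mat) + lag_term("fvc") +
    stats::rnorm(n, 0, rsd[["fvc"]])
  ratio <- 0.92 + 0.05 * (0.20 * cs + mat) + lag_term("fev1_fvc") +
    stats::rnorm(n, 0, rsd[["fev1_fvc"]])
  ratio <- pmin(pmax(ratio, 0.3), 1)
  fev1 <- ratio * fvc + lag_term("fev1") + stats::rnorm(n, 0, rsd[["fev1"]])
  fev1 <- pmin(fev1, fvc)
  fef <- 1.87 + 0.46 * (0.65 * cs + mat) + lag_term("fef2575") +
    stats::rnorm(n, 0, rsd[["fef2575"]])

  meth <- stats::rlnorm(n, spec$methylation_meanlog, spec$methylation_sdlog) +
    drop(exposures %*% spec$methylation_lag_effects)
  meth <- pmin(pmax(meth, 0), 100)
  # site-level dispersion that preserves the child-level mean exactly
  u <- matrix(stats::rlnorm(n * 17, 0, 0.3), n, 17)
  sites <- meth * 17 * u / rowSums(u)
  sites <- pmin(pmax(sites, 0), 100)
  colnames(sites) <- sprintf("gstp1_s%02d", 1:17)

  out <- covariates
  out$fev1 <- fev1
  out$fvc <- fvc
  out$fev1_fvc <- fev1 / fvc
  out$fef2575 <- fef
  cbind(out, as.data.frame(sites))
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: covariates, exposures and outcomes from one spec.
#'
#' @param spec A [truth_spec()].
#' @return List with `cohort` (covariates + outcomes), `exposures` (n x T
#'   matrix) and `truth` (the spec, echoing the true lag effects).
#' @export
simulate_cohort <- function(spec) {
  cov <- generate_covariates(spec)
  X <- generate_exposures(spec)
  cohort <- generate_outcomes(cov, X, spec)
  list(cohort = cohort, exposures = X, truth = spec)
}

#' Convert a z-scale cumulative lag effect to the raw outcome scale
#'
#' The analysis models standardized (z-score) outcomes, while simulation
#' truths enter the generator on the raw scale. This helper generates a large
#' null reference cohort internally (fixed seed, so the conversion is a pure
#' function of the spec), runs the z-score standardization regression, and
#' scales a target z-scale cumulative effect by the raw residual SD.
#'
#' @param spec A [truth_spec()] (its lag effects are ignored; a null copy is
#'   used for the reference cohort).
#' @param outcome One of `"fev1"`, `"fvc"`, `"fev1_fvc"`, `"fef2575"`.
#' @param weeks Weeks carrying the effect (e.g. `35:40`).
#' @param total_z Target cumulative effect in z-score units per ug/m3.
#' @param ref_n Size of the internal reference cohort.
#' @return Numeric vector of length `spec$T` of raw-scale lag coefficients;
#'   the attribute `"residual_sd"` carries the raw residual SD used.
#' @export
calibrate_lag_truth <- function(spec, outcome, weeks, total_z,
                                ref_n = 20000) {
  stopifnot(inherits(spec, "truth_spec"))
  ref <- spec
  ref$n_children <- as.integer(ref_n)
  ref$true_lag_effects <- NULL
  ref <- do.call(truth_spec, c(
    ref[setdiff(names(ref), c("n_children", "true_lag_effects", "seed"))],
    list(n_children = ref_n, seed = 190401L)))
  sim <- simulate_cohort(ref)
  fit <- stats::lm(stats::reformulate(
    c("child_age", "sex", "height", "race_ethnicity"), outcome),
    data = sim$cohort)
  s <- stats::sd(stats::residuals(fit))
  out <- lag_profile(spec$T, weeks, total_z * s)
  attr(out, "residual_sd") <- s
  out
}
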