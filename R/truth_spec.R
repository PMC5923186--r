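#' Simulation truth for a synthetic pregnancy cohort
#'
#' A `truth_spec` bundles every parameter of the synthetic-cohort generator:
#' the weekly PM2.5 exposure process, covariate prevalences, the outcome model
#' with its known ("true") lag effects, and the methylation law. The defaults
#' reproduce the marginal descriptives of the urban pregnancy cohort the
#' package is calibrated to: pregnancy-average PM2.5 median 10.9 ug/m3
#' (IQR 10.2-11.7), boys 52.1%, GSTP1 percent methylation median 2.26
#' (IQR 1.56-3.02), raw FEV1 mean 1.44 L, and so on.
#'
#' @param n_children Number of children in the cohort.
#' @param T Number of gestational weeks of exposure (weeks 1..T post
#'   conception; the full-term default is 40).
#' @param exposure_mean Long-run mean weekly PM2.5, ug/m3.
#' @param seasonal_amplitude Amplitude of the annual sinusoid, ug/m3.
#' @param ar1_rho AR(1) autocorrelation of week-to-week noise, in \[0, 1).
#' @param innovation_sd Innovation SD of the AR(1) noise, ug/m3.
#' @param covariate_prevalences Named list of probability vectors, one per
#'   categorical covariate block; each block must sum to 1.
#' @param true_lag_effects Named list (one element per spirometry outcome:
#'   `fev1`, `fvc`, `fev1_fvc`, `fef2575`), each a list with `girl` and `boy`
#'   numeric vectors of length `T` giving the true lag coefficient
#'   (raw outcome units per ug/m3) for each gestational week. `NULL` means
#'   all zero (the null data-generating process).
#' @param covariate_coefficients Named list: `cov_loading` (share of each raw
#'   spirometry SD carried by the age/sex/height/race component),
#'   `maternal_age` and `maternal_education` (effects of the standardized
#'   maternal covariates, as fractions of the outcome SD).
#' @param residual_sd Named numeric: residual SD, raw units, for
#'   `fev1`, `fvc`, `fev1_fvc` (the latent ratio) and `fef2575`. Setting all
#'   to zero makes the outcomes a deterministic function of covariates and
#'   exposures.
#' @param methylation_meanlog,methylation_sdlog Location/scale of the
#'   lognormal law for child-level GSTP1 percent methylation. The defaults
#'   hit the printed median exactly and balance the two quartile errors.
#' @param methylation_lag_effects Numeric vector of length `T`: true lag
#'   effect of weekly PM2.5 on percent methylation (%5mC per ug/m3), shared
#'   across sexes. `NULL` means all zero.
#' @param seed Integer seed; every generator is a pure function of the spec,
#'   so the same spec always yields bitwise-identical data.
#'
#' @return An object of class `truth_spec`.
#' @seealso [generate_exposures()], [generate_covariates()],
#'   [generate_outcomes()], [simulate_cohort()], [lag_profile()]
#' @export
truth_spec <- function(n_children = 171,
                       T = 40,
                       exposure_mean = 10.9,
                       seasonal_amplitude = 3.0,
                       ar1_rho = 0.7,
                       innovation_sd = 1.5,
                       covariate_prevalences = default_prevalences(),
                       true_lag_effects = NULL,
                       covariate_coefficients = list(
                         cov_loading = 0.70,
                         maternal_age = 0.08,
                         maternal_education = -0.12
                       ),
                       residual_sd = c(fev1 = 0.05, fvc = 0.203,
                                       fev1_fvc = 0.046, fef2575 = 0.35),
                       methylation_meanlog = log(2.26),
                       methylation_sdlog = 0.4708745,
                       methylation_lag_effects = NULL,
                       seed = 1L) {
  assert_spec(is.numeric(n_children) && length(n_children) == 1 &&
                is.finite(n_children) && n_children >= 1,
              "n_children must be a positive count")
  assert_spec(is.numeric(T) && length(T) == 1 && is.finite(T) && T >= 1 &&
                T == round(T), "T must be an integer >= 1")
  assert_spec(is.finite(exposure_mean) && is.finite(seasonal_amplitude) &&
                is.finite(innovation_sd) && innovation_sd >= 0 &&
                seasonal_amplitude >= 0,
              "exposure process parameters must be finite and non-negative")
  assert_spec(is.finite(ar1_rho) && abs(ar1_rho) < 1, "|ar1_rho| must be < 1")
  assert_spec(is.list(covariate_prevalences) &&
                length(covariate_prevalences) > 0,
              "covariate_prevalences must be a non-empty list")
  for (nm in names(covariate_prevalences)) {
    p <- covariate_prevalences[[nm]]
    assert_spec(is.numeric(p) && all(is.finite(p)) && all(p >= 0 & p <= 1),
                sprintf("prevalences for '%s' must be probabilities", nm))
    assert_spec(abs(sum(p) - 1) < 1e-6,
                sprintf("prevalences for '%s' must sum to 1", nm))
  }
  T <- as.integer(T)
  outcomes <- c("fev1", "fvc", "fev1_fvc", "fef2575")
  if (is.null(true_lag_effects)) {
    zero <- stats::setNames(
      rep(list(list(girl = numeric(T), boy = numeric(T))), 4), outcomes)
    true_lag_effects <- zero
  }
  assert_spec(all(outcomes %in% names(true_lag_effects)),
              "true_lag_effects must have one element per spirometry outcome")
  for (o in outcomes) {
    for (g in c("girl", "boy")) {
      d <- true_lag_effects[[o]][[g]]
      assert_spec(is.numeric(d) && length(d) == T && all(is.finite(d)),
                  sprintf("true lag effects for %s/%s must be length T", o, g))
    }
  }
  if (is.null(methylation_lag_effects)) methylation_lag_effects <- numeric(T)
  assert_spec(length(methylation_lag_effects) == T &&
                all(is.finite(methylation_lag_effects)),
              "methylation_lag_effects must be a finite vector of length T")
  assert_spec(all(outcomes %in% names(residual_sd)) &&
                all(is.finite(residual_sd)) && all(residual_sd >= 0),
              "residual_sd must be named, finite and non-negative")
  assert_spec(is.finite(methylation_meanlog) && is.finite(methylation_sdlog) &&
                methylation_sdlog >= 0, "methylation law parameters invalid")

  structure(list(
    n_children = as.integer(n_children), T = T,
    exposure_mean = exposure_mean,
    seasonal_amplitude = seasonal_amplitude,
    ar1_rho = ar1_rho, innovation_sd = innovation_sd,
    covariate_prevalences = covariate_prevalences,
    true_lag_effects = true_lag_effects,
    covariate_coefficients = covariate_coefficients,
    residual_sd = residual_sd,
    methylation_meanlog = methylation_meanlog,
    methylation_sdlog = methylation_sdlog,
    methylation_lag_effects = methylation_lag_effects,
    seed = as.integer(seed)
  ), class = "truth_spec")
}

#' Default categorical prevalences of the synthetic cohort
#'
#' Boys 52.1%; race/ethnicity Black 22.8% / Hispanic 65.5% / White-Other
#' 11.7%; maternal education at most 12 years 66.7%; pre/postnatal smoking
#' never 71.4% / prenatal-only 8.2% / postnatal-only 14.0% / both 6.4%;
#' child asthma 15.8%.
#'
#' @return Named list of probability vectors.
#' @export
default_prevalences <- function() {
  list(
    sex = c(girl = 0.479, boy = 0.521),
    race_ethnicity = c(Black = 0.228, Hispanic = 0.655, White_Other = 0.117),
    maternal_education = c(le12y = 0.667, gt12y = 0.333),
    smoking = c(never = 0.714, prenatal_only = 0.082,
                postnatal_only = 0.140, both = 0.064),
    asthma = c(no = 0.842, yes = 0.158)
  )
}

#' Build a lag-effect vector supported on a window
#'
#' Spreads a total (cumulative) effect uniformly over a set of gestational
#' weeks; all other weeks get zero. Convenience for writing simulation truths
#' such as "weeks 35-40 summing to -0.10 per ug/m3".
#'
#' @param T Number of gestational weeks.
#' @param weeks Integer vector of weeks carrying the effect.
#' @param total Cumulative effect summed over `weeks`.
#' @return Numeric vector of length `T`.
#' @export
lag_profile <- function(T, weeks, total) {
  assert_spec(all(weeks >= 1 & weeks <= T), "weeks must lie in 1..T")
  out <- numeric(T)
  out[weeks] <- total / length(weeks)
  out
}

#' @export
print.truth_spec <- function(x, ...) {
  cat("<truth_spec>\n")
  cat(sprintf("  n_children: %d, T: %d weeks, seed: %d\n",
              x$n_children, x$T, x$seed))
  cat(sprintf("  exposure: mean %.2f, seasonal amp %.2f, AR(1) rho %.2f, innov sd %.2f\n",
              x$exposure_mean, x$seasonal_amplitude, x$ar1_rho, x$innovation_sd))
  nz <- vapply(x$true_lag_effects,
               function(o) any(o$girl != 0) || any(o$boy != 0), logical(1))
  cat("  non-null spirometry lag effects:",
      if (any(nz)) paste(names(nz)[nz], collapse = ", ") else "none", "\n")
  invisible(x)
}
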