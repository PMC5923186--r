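#' Aggregate a daily exposure series to gestational weeks
#'
#' Week t is the mean of gestational days 7(t-1)+1 .. 7t (day 1 = first day
#' post conception). A trailing partial week with at least one day is
#' averaged over the available days; weeks with no days are returned as `NA`
#' and flagged in the `"missing_weeks"` attribute.
#'
#' @param daily Numeric vector of daily concentrations (ug/m3), indexed from
#'   conception day 1.
#' @param T Number of weeks to produce; defaults to `ceiling(length(daily)/7)`.
#' @return Numeric vector of length `T` with attribute `missing_weeks`.
#' @export
daily_to_weekly <- function(daily, T = NULL) {
  if (length(daily) == 0) {
    stop_bdlimwin("bdlimwin_empty_input", "daily exposure series is empty")
  }
  if (any(!is.finite(daily)) || any(daily < 0)) {
    stop_bdlimwin("bdlimwin_validation_error",
                  "daily concentrations must be finite and non-negative")
  }
  if (is.null(T)) T <- ceiling(length(daily) / 7)
  T <- as.integer(T)
  weekly <- vapply(seq_len(T), function(t) {
    idx <- seq.int(7L * (t - 1L) + 1L, 7L * t)
    idx <- idx[idx <= length(daily)]
    if (length(idx) == 0) NA_real_ else mean(daily[idx])
  }, numeric(1))
  attr(weekly, "missing_weeks") <- which(is.na(weekly))
  weekly
}

#' Weekly exposure matrix from a long daily table
#'
#' @param daily_long Data frame with columns `child_id`, `gestational_day`,
#'   `pm25`.
#' @param T Number of gestational weeks (default 40).
#' @return Matrix (children x weeks) with columns `pm25_wk01..`.
#' @export
weekly_exposure_matrix <- function(daily_long, T = 40) {
  need <- c("child_id", "gestational_day", "pm25")
  missing <- setdiff(need, names(daily_long))
  if (length(missing)) {
    stop_bdlimwin("bdlimwin_schema_error",
                  paste("missing columns:", paste(missing, collapse = ", ")))
  }
  ids <- unique(daily_long$child_id)
  out <- t(vapply(ids, function(id) {
    d <- daily_long[daily_long$child_id == id, ]
    d <- d[order(d$gestational_day), ]
    series <- rep(NA_real_, max(d$gestational_day))
    series[d$gestational_day] <- d$pm25
    if (anyNA(series)) {
      stop_bdlimwin("bdlimwin_validation_error",
                    sprintf("gaps in daily series for %s", id))
    }
    daily_to_weekly(series, T)
  }, numeric(T)))
  dimnames(out) <- list(ids, sprintf("pm25_wk%02d", seq_len(T)))
  out
}

#' Regression-based lung function z-scores
#'
#' For each raw spirometry outcome, fits ordinary least squares on child age,
#' sex, height and race/ethnicity (categoricals as indicator contrasts),
#' takes residuals and divides by their sample SD, yielding a column with
#' mean 0 and SD 1 describing each child's position in the cohort
#' distribution. The fitted standardization coefficients and residual SDs
#' are retained so new children can be scored consistently.
#'
#' @param data Data frame containing the outcomes and covariates.
#' @param outcomes Character vector of raw outcome columns.
#' @param covariates Character vector of adjustment covariates; use
#'   `character(0)` for intercept-only standardization.
#' @return Object of class `zscore_panel`: list with `scores` (data.frame of
#'   `z_<outcome>` columns), `coefficients` (per-outcome list) and
#'   `residual_sd` (named numeric, raw units).
#' @export
compute_lung_zscores <- function(data,
                                 outcomes = c("fev1", "fvc", "fev1_fvc",
                                              "fef2575"),
                                 covariates = c("child_age", "sex", "height",
                                                "race_ethnicity")) {
  cols <- c(outcomes, covariates)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop_bdlimwin("bdlimwin_schema_error",
                  paste("missing columns:", paste(missing, collapse = ", ")))
  }
  if (anyNA(data[cols])) {
    stop_bdlimwin("bdlimwin_validation_error",
                  "missing values among outcomes or covariates")
  }
  rhs <- if (length(covariates)) covariates else "1"
  f <- stats::reformulate(rhs, response = NULL)
  mm <- stats::model.matrix(f, data = data)
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    bad <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop_bdlimwin("bdlimwin_collinearity_error",
                  paste("collinear standardization columns:",
                        paste(bad, collapse = ", ")))
  }
  if (nrow(mm) <= ncol(mm)) {
    stop_bdlimwin("bdlimwin_validation_error",
                  "need more observations than regression coefficients")
  }
  scores <- list(); coefs <- list(); rsd <- numeric(0)
  for (o in outcomes) {
    y <- data[[o]]
    fit <- stats::lm.fit(mm, y)
    r <- fit$residuals
    s <- stats::sd(r)
    if (!is.finite(s) || s < 1e-8 * max(1, stats::sd(y))) {
      stop_bdlimwin("bdlimwin_degenerate_outcome",
                    sprintf("outcome '%s' has no residual variance", o))
    }
    scores[[paste0("z_", o)]] <- r / s
    coefs[[o]] <- fit$coefficients
    rsd[o] <- s
  }
  structure(list(scores = as.data.frame(scores),
                 coefficients = coefs,
                 residual_sd = rsd,
                 covariates = covariates),
            class = "zscore_panel")
}

#' Percent methylation at a CpG site
#'
#' 100 x methylated / (methylated + unmethylated) cytosines (%5mC).
#' Vectorized over sites.
#'
#' @param methylated,unmethylated Non-negative counts.
#' @return Numeric vector of %5mC values in \[0, 100\].
#' @export
percent_methylation <- function(methylated, unmethylated) {
  if (any(methylated < 0) || any(unmethylated < 0)) {
    stop_bdlimwin("bdlimwin_validation_error", "counts must be non-negative")
  }
  tot <- methylated + unmethylated
  if (any(tot == 0)) {
    stop_bdlimwin("bdlimwin_undefined_site",
                  "site with zero total reads has undefined %5mC")
  }
  100 * methylated / tot
}

#' Summarize the 17-site GSTP1 panel into one percent-methylation value
#'
#' Arithmetic mean of the non-missing site-level %5mC values. For a matrix
#' (children x sites) the summary is computed per row.
#'
#' @param sites Numeric vector (one child) or matrix (children x sites).
#' @return For a vector: list with `mean_5mC` and `n_missing`. For a matrix:
#'   data.frame with those two columns.
#' @export
summarize_gstp1 <- function(sites) {
  if (is.matrix(sites) || is.data.frame(sites)) {
    m <- as.matrix(sites)
    miss <- rowSums(is.na(m))
    if (any(miss == ncol(m))) {
      stop_bdlimwin("bdlimwin_missing_data",
                    "child with all sites missing")
    }
    return(data.frame(mean_5mC = rowMeans(m, na.rm = TRUE),
                      n_missing = miss))
  }
  if (all(is.na(sites))) {
    stop_bdlimwin("bdlimwin_missing_data", "all sites missing")
  }
  list(mean_5mC = mean(sites, na.rm = TRUE), n_missing = sum(is.na(sites)))
}

#' Dichotomize percent methylation at the top quartile
#'
#' The high-methylation group is the fourth quartile: values at or above the
#' sample 75th percentile. The quantile rule is linear interpolation between
#' order statistics (type 7), declared in the output.
#'
#' @param values Numeric vector of per-child mean %5mC.
#' @param type Quantile type passed to [stats::quantile()].
#' @return Object of class `methylation_summary`: list with `threshold`,
#'   logical `high_methylation`, group counts and the quantile rule.
#' @export
dichotomize_top_quartile <- function(values, type = 7) {
  if (length(values) < 4) {
    stop_bdlimwin("bdlimwin_validation_error", "need at least 4 values")
  }
  if (any(!is.finite(values))) {
    stop_bdlimwin("bdlimwin_validation_error", "values must be finite")
  }
  if (diff(range(values)) == 0) {
    stop_bdlimwin("bdlimwin_degenerate_distribution",
                  "all values identical; no quartile split exists")
  }
  thr <- unname(stats::quantile(values, 0.75, type = type))
  high <- values >= thr
  structure(list(threshold = thr,
                 high_methylation = high,
                 n_high = sum(high), n_low = sum(!high),
                 quantile_type = type),
            class = "methylation_summary")
}

#' @export
print.methylation_summary <- function(x, ...) {
  cat(sprintf(
    "<methylation_summary> threshold %.4g %%5mC (type %d): %d high / %d low\n",
    x$threshold, x$quantile_type, x$n_high, x$n_low))
  invisible(x)
}
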