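# Adjusted linear models for the methylation -> lung function arm.
# Covariate sets mirror the staged adjustment of the reported tables:
#   univariate: none
#   M1: maternal age + education (main analysis)
#   M2: M1 + child asthma (sensitivity)
#   M3: M2 + pre/postnatal tobacco-smoke category (sensitivity)
model_covariates <- function(model_id) {
  switch(model_id,
         univariate = character(0),
         M1 = c("maternal_age", "maternal_education"),
         M2 = c("maternal_age", "maternal_education", "asthma"),
         M3 = c("maternal_age", "maternal_education", "asthma", "smoking"),
         stop_bdlimwin("bdlimwin_invalid_spec",
                       sprintf("unknown model_id '%s'", model_id)))
}

#' Adjusted linear model of a z-score on high methylation
#'
#' Ordinary least squares of a lung-function z-score on the high-vs-low
#' methylation indicator plus the covariate set of the requested model,
#' on complete cases, with classical standard errors and two-sided t-test
#' p-values for the high-methylation term.
#'
#' @param data Data frame with the z-score, `high_methylation` (logical) and
#'   covariates.
#' @param outcome Name of the z-score column.
#' @param model_id One of `"univariate"`, `"M1"`, `"M2"`, `"M3"`.
#' @param stratum Label recorded in the output row (the data are used as
#'   given; subset before calling for stratified fits).
#' @return One-row data frame: outcome, model_id, stratum, term, estimate,
#'   se, p_value, n.
#' @export
fit_adjusted_lm <- function(data, outcome, model_id = "M1", stratum = "all") {
  covs <- model_covariates(model_id)
  cols <- c(outcome, "high_methylation", covs)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop_bdlimwin("bdlimwin_schema_error",
                  paste("missing columns:", paste(missing, collapse = ", ")))
  }
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  if (length(unique(d$high_methylation)) < 2) {
    stop_bdlimwin("bdlimwin_no_contrast",
                  sprintf("high_methylation constant within stratum '%s'",
                          stratum))
  }
  f <- stats::reformulate(c("high_methylation", covs), response = outcome)
  fit <- stats::lm(f, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_bdlimwin("bdlimwin_collinearity_error",
                  paste("rank-deficient design; aliased:",
                        paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  row <- grep("^high_methylation", rownames(sm))
  data.frame(outcome = outcome, model_id = model_id, stratum = stratum,
             term = "high_methylation",
             estimate = sm[row, 1], se = sm[row, 2], p_value = sm[row, 4],
             n = nrow(d), row.names = NULL)
}

#' Effect table across outcomes and adjustment models
#'
#' @param data Data frame (see [fit_adjusted_lm()]).
#' @param outcomes Z-score columns to model.
#' @param models Adjustment models to fit.
#' @return Data frame with one row per outcome x model.
#' @export
methylation_effect_table <- function(data,
                                     outcomes = c("z_fev1", "z_fvc",
                                                  "z_fev1_fvc", "z_fef2575"),
                                     models = c("univariate", "M1", "M2",
                                                "M3")) {
  rows <- list()
  for (o in outcomes) for (m in models) {
    rows[[paste(o, m)]] <- fit_adjusted_lm(data, o, m)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Sex-stratified fits and the sex x methylation interaction test
#'
#' Fits the maternal-age/education-adjusted (M1) model separately in girls
#' and boys, and a pooled M1 model augmented with sex and the
#' sex x high-methylation product term; `p_interaction` is the two-sided
#' Wald p-value of the product term.
#'
#' @param data Data frame with `sex` (levels girl, boy) in addition to the
#'   [fit_adjusted_lm()] columns.
#' @param outcome Z-score column.
#' @return Data frame with the two stratum rows plus an `interaction` row
#'   carrying `p_interaction`.
#' @export
stratified_and_interaction <- function(data, outcome) {
  if (!"sex" %in% names(data)) {
    stop_bdlimwin("bdlimwin_schema_error", "missing column: sex")
  }
  covs <- model_covariates("M1")
  rows <- list()
  for (g in levels(droplevels(as.factor(data$sex)))) {
    rows[[g]] <- fit_adjusted_lm(data[data$sex == g, , drop = FALSE],
                                 outcome, "M1", stratum = g)
  }
  cols <- c(outcome, "high_methylation", "sex", covs)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  f <- stats::reformulate(c("high_methylation * sex", covs),
                          response = outcome)
  fit <- stats::lm(f, data = d)
  sm <- summary(fit)$coefficients
  irow <- grep(":", rownames(sm))
  inter <- data.frame(outcome = outcome, model_id = "M1", stratum = "all",
                      term = rownames(sm)[irow],
                      estimate = sm[irow, 1], se = sm[irow, 2],
                      p_value = sm[irow, 4], n = nrow(d), row.names = NULL)
  out <- do.call(rbind, c(rows, list(inter), list(make.row.names = FALSE)))
  out$p_interaction <- sm[irow, 4]
  out
}
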