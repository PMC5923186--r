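#' Deviance information criterion for a BDLIM fit
#'
#' `Dbar` is the posterior mean of the deviance (-2 log-likelihood) over the
#' retained draws; `Dhat` is the deviance at the posterior means of the
#' parameters, with each weight vector averaged over draws and renormalized
#' to unit norm; `pD = Dbar - Dhat`; `DIC = Dbar + pD`.
#'
#' @param fit A [fit_bdlim()] result.
#' @return Object of class `bdlim_dic`: list with `dbar`, `pd`, `dic`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "bdlim_fit"))
  ll <- fit$draws$loglik
  if (is.null(ll) || !length(ll) || anyNA(ll)) {
    stop_bdlimwin("bdlimwin_incomplete_fit",
                  "fit has no stored log-likelihood trace")
  }
  S <- length(ll)
  if (S < 200) {
    warning("DIC computed from fewer than 200 retained draws", call. = FALSE)
  }
  dbar <- mean(-2 * ll)

  d <- fit$data
  int <- fit$internal
  n_w <- length(int$w_comp)
  w_bar <- lapply(int$w_comp, function(m) {
    v <- colMeans(m)
    v / sqrt(sum(v^2))
  })
  beta_bar <- colMeans(int$beta_comp)
  gamma_bar <- colMeans(fit$draws$gamma)
  sigma2_bar <- mean(fit$draws$sigma2)

  gidx <- as.integer(d$group)
  e <- numeric(d$n)
  for (c in seq_len(n_w)) {
    r <- which(int$wmap[gidx] == c)
    e[r] <- d$X[r, , drop = FALSE] %*% w_bar[[c]]
  }
  f <- drop(d$Z %*% gamma_bar) + beta_bar[int$bmap[gidx]] * e
  rss <- sum((d$y - f)^2)
  dhat <- d$n * log(2 * pi * sigma2_bar) + rss / sigma2_bar
  pd <- dbar - dhat
  structure(list(dbar = dbar, pd = pd, dic = dbar + pd),
            class = "bdlim_dic")
}

#' @export
print.bdlim_dic <- function(x, ...) {
  cat(sprintf("DIC %.3f  (Dbar %.3f, pD %.3f)\n", x$dic, x$dbar, x$pd))
  invisible(x)
}

#' Compare sex-interaction patterns by DIC
#'
#' Given one fit per interaction pattern on the same data, tabulates DIC,
#' DIC differences to the best model, and normalized pattern weights
#' `exp(-dDIC/2) / sum(exp(-dDIC/2))`. The weight of the winning pattern is
#' an approximate probability that it is the best-fitting pattern of effect
#' modification; it is a DIC-based pseudo-probability, not a marginal
#' -likelihood model probability, and is labelled as such in the output.
#'
#' @param fits Named list of [fit_bdlim()] results (names are patterns).
#' @return Data frame of class `pattern_comparison` with one row per
#'   pattern: `pattern`, `dic`, `pd`, `delta_dic`, `weight`, `best`.
#' @export
compare_patterns <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$pattern, character(1))
  }
  ns <- vapply(fits, function(f) f$data$n, numeric(1))
  if (length(unique(ns)) != 1) {
    stop_bdlimwin("bdlimwin_comparability_error",
                  "fits were run on data of different sizes")
  }
  y0 <- fits[[1]]$data$y
  same_y <- vapply(fits, function(f) isTRUE(all.equal(f$data$y, y0)),
                   logical(1))
  if (!all(same_y)) {
    stop_bdlimwin("bdlimwin_comparability_error",
                  "fits were run on different outcome vectors")
  }
  dic <- vapply(fits, function(f) f$dic$dic, numeric(1))
  pd <- vapply(fits, function(f) f$dic$pd, numeric(1))
  delta <- dic - min(dic)
  wt <- exp(-delta / 2)
  wt <- wt / sum(wt)
  out <- data.frame(pattern = names(fits), dic = dic, pd = pd,
                    delta_dic = delta, weight = wt,
                    best = seq_along(dic) == which.min(dic),
                    row.names = NULL)
  attr(out, "weight_definition") <-
    "DIC pseudo-probability exp(-delta_dic/2), normalized"
  class(out) <- c("pattern_comparison", "data.frame")
  out
}

#' Choose the weight-basis dimension by DIC
#'
#' Fits the model for each candidate basis dimension and returns the one
#' minimizing DIC (ties broken toward the smaller dimension, i.e. the
#' smoother weight function).
#'
#' @param y,X,Z,group As in [fit_bdlim()].
#' @param spec Base [bdlim_spec()]; its `df` is replaced by each grid value.
#' @param df_grid Integer vector of candidate dimensions.
#' @return List with `df` (chosen), `trace` (data.frame of df, dic, pd) and
#'   `best_fit` (the fit at the chosen dimension).
#' @export
select_weight_df <- function(y, X, Z = NULL, group = NULL,
                             spec = bdlim_spec(), df_grid = 3:6) {
  if (length(df_grid) == 0) {
    stop_bdlimwin("bdlimwin_invalid_spec", "df_grid is empty")
  }
  df_grid <- sort(unique(as.integer(df_grid)))
  fits <- vector("list", length(df_grid))
  for (i in seq_along(df_grid)) {
    s <- spec; s$df <- df_grid[i]
    fits[[i]] <- fit_bdlim(y, X, Z, group, s)
  }
  dic <- vapply(fits, function(f) f$dic$dic, numeric(1))
  pd <- vapply(fits, function(f) f$dic$pd, numeric(1))
  best <- which.min(dic)   # which.min returns the first (smallest df) on ties
  list(df = df_grid[best],
       trace = data.frame(df = df_grid, dic = dic, pd = pd),
       best_fit = fits[[best]])
}
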