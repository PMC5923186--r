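#' Per-week lag effect draws for one group
#'
#' Element (s, t) is `beta_g` draw s times `w_{g,t}` draw s: the posterior
#' draw of the change in the outcome per 1 ug/m3 increase in exposure at
#' gestational week t.
#'
#' @param fit A [fit_bdlim()] result.
#' @param group Group label present in the fit.
#' @return Matrix, draws x T.
#' @export
lag_effect_draws <- function(fit, group) {
  stopifnot(inherits(fit, "bdlim_fit"))
  if (!group %in% fit$groups) {
    stop_bdlimwin("bdlimwin_lookup_error",
                  sprintf("group '%s' not in fit (has: %s)", group,
                          paste(fit$groups, collapse = ", ")))
  }
  fit$draws$w[[group]] * fit$draws$beta[[group]]
}

#' Identify sensitive windows from lag-effect draws
#'
#' A gestational week is significant when the equal-tailed pointwise
#' credible interval (from draw percentiles) excludes zero; maximal runs of
#' consecutive significant weeks form the sensitive windows, reported as
#' closed integer intervals.
#'
#' @param draws Matrix of lag-effect draws (draws x T), at least 100 rows.
#' @param level Credible level in (0.5, 1).
#' @return Data frame with columns `start`, `end` (one row per window);
#'   attribute `"weekly"` carries the per-week interval table.
#' @export
identify_sensitive_windows <- function(draws, level = 0.95) {
  if (!(is.numeric(level) && length(level) == 1 && level > 0.5 && level < 1)) {
    stop_bdlimwin("bdlimwin_invalid_level", "level must lie in (0.5, 1)")
  }
  draws <- as.matrix(draws)
  if (nrow(draws) < 100) {
    stop_bdlimwin("bdlimwin_validation_error",
                  "need at least 100 draws for interval estimates")
  }
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  lower <- qs[1, ]; upper <- qs[2, ]
  sig <- lower > 0 | upper < 0
  out <- runs_to_windows(sig)
  attr(out, "weekly") <- data.frame(week = seq_len(ncol(draws)),
                                    lower = lower, upper = upper,
                                    significant = sig)
  attr(out, "level") <- level
  out
}

#' Cumulative effect over gestation
#'
#' For each posterior draw, the cumulative effect is the sum of the weekly
#' lag effects, `CE = beta * sum_t w_t`: the outcome change per 1 ug/m3
#' increase in exposure sustained across the whole pregnancy. Reported with
#' an equal-tailed credible interval.
#'
#' @param draws Lag-effect draw matrix (draws x T).
#' @param level Credible level.
#' @return List with `mean`, `lower`, `upper`, `level` and the `draws` of CE.
#' @export
cumulative_effect <- function(draws, level = 0.95) {
  draws <- as.matrix(draws)
  if (nrow(draws) == 0 || ncol(draws) == 0) {
    stop_bdlimwin("bdlimwin_empty_input", "empty draw matrix")
  }
  ce <- rowSums(draws)
  alpha <- (1 - level) / 2
  q <- stats::quantile(ce, c(alpha, 1 - alpha), names = FALSE)
  list(mean = mean(ce), lower = q[1], upper = q[2], level = level, draws = ce)
}

#' Full window report for a fitted model
#'
#' Collects, per group: posterior mean weekly lag effects with pointwise
#' credible bounds, the sensitive window set, and the cumulative effect.
#'
#' @param fit A [fit_bdlim()] result.
#' @param level Credible level for all intervals.
#' @return Object of class `window_report`.
#' @export
window_report <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "bdlim_fit"))
  weekly <- list(); windows <- list(); cum <- list()
  for (g in fit$groups) {
    dr <- lag_effect_draws(fit, g)
    win <- identify_sensitive_windows(dr, level)
    wk <- attr(win, "weekly")
    wk$mean <- colMeans(dr)
    wk$group <- g
    weekly[[g]] <- wk[c("group", "week", "mean", "lower", "upper",
                        "significant")]
    if (nrow(win)) win$group <- g
    windows[[g]] <- win
    ce <- cumulative_effect(dr, level)
    cum[[g]] <- data.frame(group = g, mean = ce$mean, lower = ce$lower,
                           upper = ce$upper)
  }
  structure(list(
    groups = fit$groups, level = level, pattern = fit$pattern,
    weekly = do.call(rbind, c(weekly, list(make.row.names = FALSE))),
    windows = do.call(rbind, c(windows, list(make.row.names = FALSE))),
    cumulative = do.call(rbind, c(cum, list(make.row.names = FALSE)))
  ), class = "window_report")
}

#' @export
print.window_report <- function(x, ...) {
  cat(sprintf("<window_report> pattern '%s', %.0f%% pointwise intervals\n",
              x$pattern, 100 * x$level))
  for (g in x$groups) {
    wg <- x$windows[x$windows$group == g, , drop = FALSE]
    lab <- if (nrow(wg) == 0) "none" else
      paste(sprintf("%d-%d", wg$start, wg$end), collapse = ", ")
    cg <- x$cumulative[x$cumulative$group == g, ]
    cat(sprintf("  %s: windows %s; CE %.3f (%.3f, %.3f)\n",
                g, lab, cg$mean, cg$lower, cg$upper))
  }
  invisible(x)
}

#' Tidy per-week lag-effect table
#'
#' @param report A [window_report()].
#' @return Data frame with columns `group`, `week`, `mean`, `lower`,
#'   `upper`, `in_window`.
#' @export
lag_curve_table <- function(report) {
  stopifnot(inherits(report, "window_report"))
  out <- report$weekly
  names(out)[names(out) == "significant"] <- "in_window"
  out
}

#' Lag-effect curves with credible bands
#'
#' One panel per group: posterior mean weekly effect (solid line) with the
#' pointwise credible band shaded; weeks whose band excludes zero are the
#' sensitive windows.
#'
#' @param report A [window_report()].
#' @return A ggplot object.
#' @export
plot_lag_curves <- function(report) {
  tab <- lag_curve_table(report)
  ggplot2::ggplot(tab, ggplot2::aes(x = week, y = mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Gestational week",
                  y = "Effect per 1 µg/m³ PM2.5",
                  title = sprintf("Weekly lag effects (%.0f%% pointwise CI)",
                                  100 * report$level)) +
    ggplot2::theme_minimal()
}

#' @export
plot.window_report <- function(x, ...) plot_lag_curves(x)
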