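# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed errors so callers/tests can condition on failure mode
stop_bdlimwin <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "bdlimwin_error", "error", "condition")))
}

assert_spec <- function(cond, msg) {
  if (!isTRUE(cond)) stop_bdlimwin("bdlimwin_invalid_spec", msg)
}

# deterministic sub-seed derivation; keeps the result a valid 32-bit integer
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L))
}

# effective sample size via initial positive autocorrelation sum
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) < 1e-300) return(n)
  a <- stats::acf(x, lag.max = min(200L, n - 1L), plot = FALSE)$acf[-1]
  cut <- which(a < 0.05)
  k <- if (length(cut)) cut[1] - 1L else length(a)
  s <- if (k >= 1) sum(a[seq_len(k)]) else 0
  max(1, n / (1 + 2 * s))
}

# maximal runs of TRUE as closed integer intervals
runs_to_windows <- function(flag) {
  if (!any(flag)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

col_vars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

# full-precision numeric formatting for lossless text serialization
fmt_full <- function(x) sprintf("%.17g", x)
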