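#' BDLIM model and sampler settings
#'
#' The Bayesian distributed lag interaction model is
#' \deqn{y_i = z_i' \gamma + \beta_{g(i)} \sum_t w_{g(i),t} x_{i,t} +
#'   \epsilon_i, \quad \epsilon_i \sim N(0, \sigma^2),}
#' with the lag function factored into a unit-L2-norm weight vector
#' `w_g` (timing) spanned by a natural cubic spline basis, and a scalar
#' within-window effect `beta_g` (magnitude). The interaction `pattern` says
#' which components are shared across the two levels of the effect modifier
#' (sex): `"n"` shares both weights and effect, `"b"` shares weights with
#' group-specific effects, `"w"` has group-specific weights with a shared
#' effect, `"bw"` lets both differ.
#'
#' Priors: `(gamma, beta)` jointly Normal(0, `prior_var` * sigma^2 * I)
#' (conjugate normal-inverse-gamma scaling), `sigma^2` ~
#' Inverse-Gamma(`sigma_shape`, `sigma_scale`), and spline coefficients
#' `xi_g` ~ Normal(0, I) restricted to the half-space `sum_t w_t >= 0`
#' (the sign convention that identifies the (beta, w) pair).
#'
#' @param pattern One of `"n"`, `"b"`, `"w"`, `"bw"`.
#' @param df Weight-basis dimension K (see [build_weight_basis()]).
#' @param prior_var Prior variance multiplier c^2 for the regression
#'   coefficients (on standardized data the default 100 is weakly
#'   informative).
#' @param sigma_shape,sigma_scale Inverse-gamma shape/scale for sigma^2.
#' @param iter,burnin,thin MCMC iterations, burn-in, thinning.
#' @param proposal_sd Initial random-walk Metropolis scale for the spline
#'   coefficients; adapted during burn-in toward 20-40% acceptance and then
#'   frozen.
#' @param seed Integer seed recorded in the fit.
#' @return Object of class `bdlim_spec`.
#' @export
bdlim_spec <- function(pattern = c("n", "b", "w", "bw"),
                       df = 5,
                       prior_var = 100,
                       sigma_shape = 0.01,
                       sigma_scale = 0.01,
                       iter = 10000,
                       burnin = 5000,
                       thin = 5,
                       proposal_sd = 0.25,
                       seed = 1L) {
  pattern <- match.arg(pattern)
  assert_spec(df >= 2 && df == round(df), "df must be an integer >= 2")
  assert_spec(iter > burnin && burnin >= 0, "need iter > burnin >= 0")
  assert_spec(thin >= 1 && thin == round(thin), "thin must be a positive integer")
  assert_spec(prior_var > 0 && sigma_shape > 0 && sigma_scale > 0,
              "prior parameters must be positive")
  assert_spec(proposal_sd > 0, "proposal_sd must be positive")
  structure(list(pattern = pattern, df = as.integer(df),
                 prior_var = prior_var,
                 sigma_shape = sigma_shape, sigma_scale = sigma_scale,
                 iter = as.integer(iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), proposal_sd = proposal_sd,
                 seed = as.integer(seed)),
            class = "bdlim_spec")
}

#' Fit a Bayesian distributed lag interaction model
#'
#' MCMC for the model described in [bdlim_spec()]: conjugate Gibbs updates
#' for the regression coefficients (covariates plus within-window effects)
#' and the residual variance, and an adaptive random-walk Metropolis update
#' for the spline coefficients of each weight function, which is normalized
#' to unit L2 norm. Every retained weight draw satisfies
#' `sum(w^2) == 1` and `sum(w) >= 0`.
#'
#' @param y Outcome vector (typically a spirometry z-score or percent
#'   methylation), length n.
#' @param X Exposure matrix, n x T, weekly means in ug/m3.
#' @param Z Covariate design matrix (n x p). `NULL` gives an intercept only;
#'   otherwise supply a full-rank matrix that already contains an intercept
#'   column if one is wanted.
#' @param group Factor with two levels (e.g. girl/boy) or `NULL` for a
#'   single-group fit (pattern `"n"` only).
#' @param spec A [bdlim_spec()].
#' @param fixed_weights Diagnostic mode: a unit-norm weight vector (or named
#'   list per group level) held fixed, reducing the sampler to the conjugate
#'   Gibbs updates. Used to validate the sampler against closed forms.
#' @return Object of class `bdlim_fit` with per-group posterior draws
#'   (`w` draws S x T, `beta` length S, `gamma` S x p, `sigma2`, `loglik`),
#'   acceptance rates, effective sample sizes, and a DIC record.
#' @export
fit_bdlim <- function(y, X, Z = NULL, group = NULL, spec = bdlim_spec(),
                      fixed_weights = NULL) {
  stopifnot(inherits(spec, "bdlim_spec"))
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y); T <- ncol(X)
  if (nrow(X) != n) stop_bdlimwin("bdlimwin_shape_error",
                                  "X must have one row per element of y")
  if (any(!is.finite(y)) || any(!is.finite(X))) {
    stop_bdlimwin("bdlimwin_validation_error", "y and X must be finite")
  }
  if (max(col_vars(X)) < 1e-12) {
    stop_bdlimwin("bdlimwin_unidentifiable_exposure",
                  "every exposure week has zero variance across subjects")
  }
  if (is.null(Z)) Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Z <- as.matrix(Z)
  if (nrow(Z) != n) stop_bdlimwin("bdlimwin_shape_error",
                                  "Z must have one row per element of y")
  p <- ncol(Z)
  qz <- qr(Z)
  if (qz$rank < p) {
    bad <- colnames(Z)[qz$pivot[(qz$rank + 1):p]]
    stop_bdlimwin("bdlimwin_collinearity_error",
                  paste("collinear covariate columns:",
                        paste(bad, collapse = ", ")))
  }
  if (is.null(group)) group <- factor(rep("all", n))
  group <- droplevels(as.factor(group))
  lv <- levels(group)
  if (spec$pattern != "n" && length(lv) != 2) {
    stop_bdlimwin("bdlimwin_invalid_spec",
                  "patterns b, w, bw need a two-level group")
  }
  if (length(lv) > 2) {
    stop_bdlimwin("bdlimwin_invalid_spec", "only a binary modifier is supported")
  }

  # Center exposure columns when Z spans a constant: e = X w then has mean
  # near 0 whatever the weight shape, decoupling the weight update from the
  # intercept (a pure reparametrization of the intercept; beta, w, and the
  # lag effects are unchanged).
  has_const <- max(abs(stats::lm.fit(Z, rep(1, n))$residuals)) < 1e-8
  exposure_center <- if (has_const) colMeans(X) else rep(0, T)
  X <- sweep(X, 2, exposure_center)

  share_w <- spec$pattern %in% c("n", "b")
  share_b <- spec$pattern %in% c("n", "w")
  n_w <- if (share_w) 1L else length(lv)
  n_b <- if (share_b) 1L else length(lv)
  wmap <- if (share_w) rep(1L, length(lv)) else seq_along(lv)
  bmap <- if (share_b) rep(1L, length(lv)) else seq_along(lv)
  names(wmap) <- names(bmap) <- lv
  gidx <- as.integer(group)

  K <- spec$df
  B <- build_weight_basis(T, K)
  c2 <- spec$prior_var
  a0 <- spec$sigma_shape; b0 <- spec$sigma_scale

  rows_w <- lapply(seq_len(n_w), function(c) which(wmap[gidx] == c))
  XB <- lapply(rows_w, function(r) X[r, , drop = FALSE] %*% B)
  y_w <- lapply(rows_w, function(r) y[r])
  bcol_row <- p + bmap[gidx]            # design column of each row's beta
  bcomp_rows <- lapply(seq_len(n_b), function(c) which(bmap[gidx] == c))

  sample_weights <- is.null(fixed_weights)
  set.seed(spec$seed)

  # state; initialize each weight component at the unconstrained
  # distributed-lag least-squares solution in basis space (covariates
  # partialled out), so the chain starts near the likelihood mode
  xi <- vector("list", n_w); w <- vector("list", n_w)
  if (sample_weights) {
    for (c in seq_len(n_w)) {
      r <- rows_w[[c]]
      xi0 <- tryCatch({
        Zr <- Z[r, , drop = FALSE]
        ry <- stats::lm.fit(Zr, y[r])$residuals
        rXB <- stats::lm.fit(Zr, XB[[c]])$residuals
        eta <- stats::lm.fit(rXB, ry)$coefficients
        eta[!is.finite(eta)] <- 0
        if (sum(abs(eta)) < 1e-12) stop("flat")
        eta
      }, error = function(e) qr.solve(B, rep(1 / sqrt(T), T)))
      v0 <- drop(B %*% xi0)
      if (sum(v0) < 0) { xi0 <- -xi0; v0 <- -v0 }
      nv0 <- sqrt(sum(v0^2))
      if (nv0 < 1e-12) {
        xi0 <- qr.solve(B, rep(1 / sqrt(T), T))
        v0 <- drop(B %*% xi0); nv0 <- sqrt(sum(v0^2))
      }
      # scale so the prior sees a typical magnitude
      xi[[c]] <- xi0 / nv0
      w[[c]] <- v0 / nv0
    }
  } else {
    fw <- fixed_weights
    if (!is.list(fw)) fw <- stats::setNames(rep(list(fw), length(lv)), lv)
    for (c in seq_len(n_w)) {
      g_of_c <- lv[which(wmap == c)[1]]
      wc <- as.numeric(fw[[g_of_c]])
      if (length(wc) != T) stop_bdlimwin("bdlimwin_shape_error",
                                         "fixed weight vector must have length T")
      w[[c]] <- wc / sqrt(sum(wc^2))
    }
  }
  e <- numeric(n)
  for (c in seq_len(n_w)) e[rows_w[[c]]] <- X[rows_w[[c]], , drop = FALSE] %*% w[[c]]

  build_D <- function(e) {
    if (n_b == 1L) return(cbind(Z, lag = e))
    E <- matrix(0, n, n_b)
    for (j in seq_len(n_b)) E[bcomp_rows[[j]], j] <- e[bcomp_rows[[j]]]
    cbind(Z, E)
  }
  pt <- p + n_b

  # Conjugate bookkeeping for the current weight state. The spline
  # coefficients are updated by Metropolis on the marginal likelihood with
  # (gamma, beta, sigma2) integrated out (normal-inverse-gamma conjugacy),
  # so the within-window effect adapts instantly to a proposed window shape;
  # (gamma, beta, sigma2) are then drawn from their exact joint conditional.
  a_star <- a0 + n / 2
  yty <- sum(y^2)
  conj_state <- function(e) {
    D <- build_D(e)
    M <- crossprod(D); diag(M) <- diag(M) + 1 / c2
    ch <- chol(M)
    Dty <- crossprod(D, y)
    m <- backsolve(ch, forwardsolve(t(ch), Dty))
    b_star <- b0 + 0.5 * (yty - sum(m * Dty))
    list(D = D, ch = ch, m = m, b_star = b_star,
         logdet = 2 * sum(log(diag(ch))))
  }
  st <- conj_state(e)

  S_keep <- (spec$iter - spec$burnin) %/% spec$thin
  w_store <- lapply(seq_len(n_w), function(c) matrix(NA_real_, S_keep, T))
  beta_store <- matrix(NA_real_, S_keep, n_b)
  gamma_store <- matrix(NA_real_, S_keep, p,
                        dimnames = list(NULL, colnames(Z)))
  sigma2_store <- numeric(S_keep)
  ll_store <- numeric(S_keep)

  scale_c <- rep(spec$proposal_sd, n_w)
  prop_total <- acc_total <- rep(0L, n_w)       # post burn-in
  prop_win <- acc_win <- rep(0L, n_w)           # adaptation window

  s_out <- 0L
  for (it in seq_len(spec$iter)) {
    # --- xi_c: collapsed random-walk Metropolis, support sum(w) >= 0
    if (sample_weights) {
      for (c in seq_len(n_w)) {
        r <- rows_w[[c]]
        # proposal mixture: mostly local steps at the adapted scale, with an
        # occasional 5x step to cross between weight-shape modes
        step <- scale_c[c] * if (stats::runif(1) < 0.1) 5 else 1
        xs <- xi[[c]] + step * stats::rnorm(K)
        v <- drop(B %*% xs)
        nv <- sqrt(sum(v^2))
        prop_win[c] <- prop_win[c] + 1L
        if (it > spec$burnin) prop_total[c] <- prop_total[c] + 1L
        if (nv > 0 && sum(v) >= 0) {
          e_prop <- e
          e_prop[r] <- drop(XB[[c]] %*% xs) / nv
          st_prop <- conj_state(e_prop)
          log_acc <- 0.5 * (st$logdet - st_prop$logdet) -
            a_star * (log(st_prop$b_star) - log(st$b_star)) +
            0.5 * (sum(xi[[c]]^2) - sum(xs^2))
          if (log(stats::runif(1)) < log_acc) {
            xi[[c]] <- xs; w[[c]] <- v / nv
            e <- e_prop; st <- st_prop
            acc_win[c] <- acc_win[c] + 1L
            if (it > spec$burnin) acc_total[c] <- acc_total[c] + 1L
          }
        }
      }
      # adapt proposal scales during burn-in only
      if (it <= spec$burnin && it %% 50 == 0) {
        rate <- acc_win / pmax(prop_win, 1L)
        scale_c <- pmin(pmax(scale_c * exp(0.8 * (rate - 0.3)), 1e-4), 10)
        prop_win[] <- 0L; acc_win[] <- 0L
      }
    }

    # --- (sigma2, gamma, beta) | w: exact joint conditional draw
    sigma2 <- 1 / stats::rgamma(1, shape = a_star, rate = st$b_star)
    theta <- st$m + sqrt(sigma2) * backsolve(st$ch, stats::rnorm(pt))

    # --- store
    if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0L) {
      s_out <- s_out + 1L
      f <- drop(st$D %*% theta)
      rss_cur <- sum((y - f)^2)
      for (c in seq_len(n_w)) w_store[[c]][s_out, ] <- w[[c]]
      beta_store[s_out, ] <- theta[(p + 1):pt]
      gamma_store[s_out, ] <- theta[1:p]
      sigma2_store[s_out] <- sigma2
      ll_store[s_out] <- -0.5 * n * log(2 * pi * sigma2) -
        rss_cur / (2 * sigma2)
    }
  }

  acc_rate <- ifelse(prop_total > 0, acc_total / prop_total, NA_real_)
  ess_beta <- apply(beta_store, 2, ess)
  converged <- all(ess_beta >= 100)
  if (!converged) {
    warning("effective sample size of a within-window effect is below 100; ",
            "treat this fit as non-convergent", call. = FALSE)
  }

  draws <- list(
    w = stats::setNames(lapply(lv, function(g) w_store[[wmap[g]]]), lv),
    beta = stats::setNames(lapply(lv, function(g) beta_store[, bmap[g]]), lv),
    gamma = gamma_store,
    sigma2 = sigma2_store,
    loglik = ll_store
  )
  fit <- structure(list(
    draws = draws,
    internal = list(w_comp = w_store, beta_comp = beta_store,
                    wmap = wmap, bmap = bmap),
    pattern = spec$pattern, groups = lv,
    spec = spec, basis = B,
    data = list(y = y, X = X, Z = Z, group = group, n = n, T = T, p = p,
                exposure_center = exposure_center),
    acceptance = stats::setNames(acc_rate, paste0("w", seq_len(n_w))),
    ess_beta = stats::setNames(ess_beta,
                               if (n_b == 1) "shared" else lv),
    converged = converged,
    fixed_weights = !sample_weights
  ), class = "bdlim_fit")
  fit$dic <- compute_dic(fit)
  fit
}

#' @export
print.bdlim_fit <- function(x, ...) {
  cat(sprintf("<bdlim_fit> pattern '%s', n = %d, T = %d, df = %d, %d draws\n",
              x$pattern, x$data$n, x$data$T, x$spec$df,
              length(x$draws$sigma2)))
  for (g in x$groups) {
    cat(sprintf("  beta[%s]: mean %.4f (ESS %.0f)\n", g,
                mean(x$draws$beta[[g]]),
                ess(x$draws$beta[[g]])))
  }
  cat(sprintf("  DIC %.2f (pD %.2f)%s\n", x$dic$dic, x$dic$pd,
              if (x$converged) "" else "  [non-convergent]"))
  invisible(x)
}
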