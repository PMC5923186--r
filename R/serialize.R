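# Text serialization. Numeric tables are written with 17 significant digits
# so draws round-trip losslessly through the delimiter-separated files.

write_table_full <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_full(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a fitted BDLIM to a directory of text files
#'
#' Draw matrices go to CSV (full precision); the spec, seed, acceptance
#' rates and DIC go to a YAML metadata document. [read_bdlim_fit()] restores
#' the draws and metadata losslessly.
#'
#' @param fit A [fit_bdlim()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bdlim_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "bdlim_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  int <- fit$internal
  for (c in seq_along(int$w_comp)) {
    w <- as.data.frame(int$w_comp[[c]])
    names(w) <- sprintf("wk%02d", seq_len(ncol(w)))
    write_table_full(w, file.path(dir, sprintf("weights_comp%d.csv", c)))
  }
  bc <- as.data.frame(int$beta_comp)
  names(bc) <- sprintf("beta%d", seq_len(ncol(bc)))
  write_table_full(bc, file.path(dir, "beta.csv"))
  write_table_full(as.data.frame(fit$draws$gamma),
                   file.path(dir, "gamma.csv"))
  write_table_full(data.frame(sigma2 = fit$draws$sigma2,
                              loglik = fit$draws$loglik),
                   file.path(dir, "scalars.csv"))
  meta <- list(
    pattern = fit$pattern,
    groups = as.list(fit$groups),
    wmap = as.list(fit$internal$wmap),
    bmap = as.list(fit$internal$bmap),
    spec = unclass(fit$spec),
    n = fit$data$n, T = fit$data$T,
    acceptance = as.list(fit$acceptance),
    ess_beta = as.list(fit$ess_beta),
    converged = fit$converged,
    dic = list(dbar = fit$dic$dbar, pd = fit$dic$pd, dic = fit$dic$dic)
  )
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"),
                   precision = 17L)
  invisible(dir)
}

#' Read a serialized BDLIM fit
#'
#' @param dir Directory written by [write_bdlim_fit()].
#' @return List with `draws` (per-group, as in a live fit), `internal`
#'   component draws, and `meta` (spec echo, DIC, acceptance rates).
#' @export
read_bdlim_fit <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  wfiles <- sort(list.files(dir, "^weights_comp", full.names = TRUE))
  w_comp <- lapply(wfiles, function(f) {
    as.matrix(utils::read.csv(f, colClasses = "numeric"))
  })
  beta_comp <- as.matrix(utils::read.csv(file.path(dir, "beta.csv"),
                                         colClasses = "numeric"))
  gamma <- as.matrix(utils::read.csv(file.path(dir, "gamma.csv"),
                                     colClasses = "numeric"))
  sc <- utils::read.csv(file.path(dir, "scalars.csv"),
                        colClasses = "numeric")
  groups <- unlist(meta$groups)
  wmap <- unlist(meta$wmap); bmap <- unlist(meta$bmap)
  draws <- list(
    w = stats::setNames(lapply(groups, function(g) w_comp[[wmap[[g]]]]),
                        groups),
    beta = stats::setNames(lapply(groups, function(g) beta_comp[, bmap[[g]]]),
                           groups),
    gamma = gamma, sigma2 = sc$sigma2, loglik = sc$loglik
  )
  list(draws = draws,
       internal = list(w_comp = w_comp, beta_comp = beta_comp,
                       wmap = wmap, bmap = bmap),
       meta = meta)
}

#' Write a cohort table (or any data frame) as CSV
#' @param data Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  write_table_full(data, path)
  invisible(path)
}

#' Write an exposure matrix as CSV with a child_id column
#' @param exposures Matrix from [generate_exposures()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_exposures <- function(exposures, path) {
  df <- data.frame(child_id = rownames(exposures), exposures,
                   check.names = FALSE, row.names = NULL)
  write_table_full(df, path)
  invisible(path)
}

#' Read an exposure matrix written by [write_exposures()]
#' @param path CSV file.
#' @return Numeric matrix with child ids as rownames.
#' @export
read_exposures <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
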