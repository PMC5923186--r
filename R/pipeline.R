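VALID_OUTCOMES <- c("fev1", "fvc", "fev1_fvc", "fef2575")
VALID_PATTERNS <- c("n", "b", "w", "bw")

#' Configuration for an end-to-end pipeline run
#'
#' Validated up front; the resolved configuration (with the seed and package
#' version) is written next to the outputs so every run is reproducible.
#'
#' @param out_dir Output directory.
#' @param seed Global seed; expanded into fixed per-stage sub-seeds so stages
#'   can be re-run independently with unchanged results.
#' @param simulation Named list of [truth_spec()] arguments (e.g.
#'   `n_children`, `true_lag_effects`); used when no input files are given.
#' @param cohort_file,exposure_file Optional CSV inputs (as written by
#'   [write_cohort()] / [write_exposures()]) used instead of simulation.
#' @param outcomes Spirometry outcomes to model.
#' @param patterns Interaction patterns to fit and compare.
#' @param df Weight-basis dimension.
#' @param level Credible level for windows and cumulative effects.
#' @param mcmc Named list: `iter`, `burnin`, `thin`.
#' @param methylation_bdlim Also fit the distributed lag model for GSTP1
#'   percent methylation (overall sample)?
#' @param figures Write lag-curve figures (PDF)? Figure files embed
#'   creation timestamps, so runs that must be byte-identical can disable
#'   them.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            simulation = list(),
                            cohort_file = NULL,
                            exposure_file = NULL,
                            outcomes = VALID_OUTCOMES,
                            patterns = VALID_PATTERNS,
                            df = 5,
                            level = 0.95,
                            mcmc = list(iter = 10000, burnin = 5000,
                                        thin = 5),
                            methylation_bdlim = TRUE,
                            figures = TRUE) {
  bad <- setdiff(outcomes, VALID_OUTCOMES)
  if (length(bad)) {
    stop_bdlimwin("bdlimwin_schema_error",
                  paste("unknown outcome(s):", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(patterns, VALID_PATTERNS)
  if (length(bad)) {
    stop_bdlimwin("bdlimwin_schema_error",
                  paste("unknown pattern(s):", paste(bad, collapse = ", ")))
  }
  assert_spec(is.numeric(level) && level > 0.5 && level < 1,
              "level must lie in (0.5, 1)")
  assert_spec(length(outcomes) >= 1, "need at least one outcome")
  for (f in c(cohort_file, exposure_file)) {
    if (!is.null(f) && !file.exists(f)) {
      stop_bdlimwin("bdlimwin_schema_error",
                    sprintf("input file not found: %s", f))
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulation = simulation,
                 cohort_file = cohort_file, exposure_file = exposure_file,
                 outcomes = outcomes, patterns = patterns,
                 df = as.integer(df), level = level, mcmc = mcmc,
                 methylation_bdlim = isTRUE(methylation_bdlim),
                 figures = isTRUE(figures)),
            class = "pipeline_config")
}

#' Run the full sensitive-window analysis pipeline
#'
#' Stages: simulate (or load) the cohort and weekly exposures; preprocess
#' (z-scores, GSTP1 summary, top-quartile dichotomization); fit the
#' distributed lag interaction model per outcome x pattern; compare patterns
#' by DIC; produce window and cumulative-effect reports for the best
#' pattern; fit the methylation-outcome linear models. Every table is
#' written as CSV, fits as text archives, and a manifest with MD5 checksums
#' lists every artifact.
#'
#' @param config A [pipeline_config()] (or the path of a YAML file with its
#'   fields).
#' @return Invisibly, a list with the manifest, pattern comparisons and
#'   window reports.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "log.txt")
  logmsg <- function(...) {
    line <- sprintf(...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  stage <- function(name, expr) {
    logmsg("[stage] %s", name)
    tryCatch(expr, error = function(e) {
      logmsg("[failed] %s: %s", name, conditionMessage(e))
      stop_bdlimwin("bdlimwin_stage_error",
                    sprintf("stage '%s' failed: %s", name,
                            conditionMessage(e)))
    })
  }

  resolved <- unclass(config)
  resolved$out_dir <- NULL    # the echo lives inside the directory it names
  resolved$package_version <- as.character(utils::packageVersion("bdlimwin"))
  yaml::write_yaml(resolved, file.path(out, "config.yaml"))

  # --- simulate or load -----------------------------------------------------
  sim <- stage("simulate", {
    if (!is.null(config$cohort_file)) {
      cohort <- utils::read.csv(config$cohort_file)
      exposures <- read_exposures(config$exposure_file)
      list(cohort = cohort, exposures = exposures, truth = NULL)
    } else {
      spec <- do.call(truth_spec, c(config$simulation,
                                    list(seed = config$seed)))
      s <- simulate_cohort(spec)
      truth_tab <- do.call(rbind, lapply(names(spec$true_lag_effects),
        function(o) {
          do.call(rbind, lapply(c("girl", "boy"), function(g) {
            data.frame(outcome = o, group = g, week = seq_len(spec$T),
                       delta = spec$true_lag_effects[[o]][[g]])
          }))
        }))
      write_cohort(truth_tab, file.path(out, "truth_lag_effects.csv"))
      s
    }
  })
  cohort <- sim$cohort
  exposures <- sim$exposures
  write_cohort(cohort, file.path(out, "cohort.csv"))
  write_exposures(exposures, file.path(out, "exposures.csv"))

  # --- preprocess -----------------------------------------------------------
  analysis <- stage("preprocess", {
    zp <- compute_lung_zscores(cohort)
    site_cols <- grep("^gstp1_s", names(cohort), value = TRUE)
    gs <- summarize_gstp1(cohort[, site_cols])
    dich <- dichotomize_top_quartile(gs$mean_5mC)
    a <- cbind(cohort, zp$scores)
    a$mean_5mC <- gs$mean_5mC
    a$high_methylation <- dich$high_methylation
    coef_tab <- do.call(rbind, lapply(names(zp$coefficients), function(o) {
      data.frame(outcome = o, term = names(zp$coefficients[[o]]),
                 estimate = zp$coefficients[[o]],
                 residual_sd = zp$residual_sd[[o]], row.names = NULL)
    }))
    write_cohort(coef_tab, file.path(out, "zscore_coefficients.csv"))
    logmsg("methylation threshold %.4g %%5mC (%d high / %d low)",
           dich$threshold, dich$n_high, dich$n_low)
    write_cohort(a, file.path(out, "analysis.csv"))
    a
  })

  # --- distributed lag fits -------------------------------------------------
  Z_spiro <- stats::model.matrix(~ maternal_age + maternal_education,
                                 data = analysis)
  group <- factor(analysis$sex, levels = c("girl", "boy"))
  mc <- config$mcmc
  comparisons <- list(); reports <- list(); ce_rows <- list()

  fit_idx <- 0L
  for (o in config$outcomes) {
    y <- analysis[[paste0("z_", o)]]
    fits <- list()
    for (pat in config$patterns) {
      fit_idx <- fit_idx + 1L
      fits[[pat]] <- stage(sprintf("fit %s / %s", o, pat), {
        sp <- bdlim_spec(pattern = pat, df = config$df,
                         iter = mc$iter, burnin = mc$burnin, thin = mc$thin,
                         seed = sub_seed(config$seed, 100L + fit_idx))
        f <- fit_bdlim(y, exposures, Z_spiro,
                       group = if (pat == "n") NULL else group, spec = sp)
        write_bdlim_fit(f, file.path(out, "fits", paste(o, pat, sep = "_")))
        f
      })
    }
    if (length(fits) > 1) {
      cmp <- compare_patterns(fits)
      write_cohort(cmp, file.path(out, sprintf("pattern_comparison_%s.csv", o)))
      comparisons[[o]] <- cmp
      best <- cmp$pattern[cmp$best][1]
    } else {
      best <- names(fits)[1]
    }
    rep <- window_report(fits[[best]], level = config$level)
    reports[[o]] <- rep
    write_cohort(lag_curve_table(rep),
                 file.path(out, sprintf("lag_curves_%s.csv", o)))
    write_cohort(rep$windows, file.path(out, sprintf("windows_%s.csv", o)))
    ce <- rep$cumulative
    ce$outcome <- o; ce$pattern <- best
    ce_rows[[o]] <- ce
    if (config$figures) {
      ggplot2::ggsave(file.path(out, sprintf("fig_%s.pdf", o)),
                      plot_lag_curves(rep), width = 7, height = 4)
    }
  }
  write_cohort(do.call(rbind, c(ce_rows, list(make.row.names = FALSE))),
               file.path(out, "cumulative_effects.csv"))

  # --- methylation as distributed-lag outcome -------------------------------
  if (config$methylation_bdlim) {
    stage("fit gstp1", {
      Zm <- stats::model.matrix(
        ~ child_age + sex + race_ethnicity + maternal_age +
          maternal_education, data = analysis)
      sp <- bdlim_spec(pattern = "n", df = config$df,
                       iter = mc$iter, burnin = mc$burnin, thin = mc$thin,
                       seed = sub_seed(config$seed, 99L))
      fm <- fit_bdlim(analysis$mean_5mC, exposures, Zm, spec = sp)
      write_bdlim_fit(fm, file.path(out, "fits", "gstp1_n"))
      repm <- window_report(fm, level = config$level)
      write_cohort(lag_curve_table(repm),
                   file.path(out, "lag_curves_gstp1.csv"))
      write_cohort(repm$windows, file.path(out, "windows_gstp1.csv"))
      if (config$figures) {
        ggplot2::ggsave(file.path(out, "fig_gstp1.pdf"),
                        plot_lag_curves(repm), width = 5, height = 4)
      }
      reports[["gstp1"]] <- repm
    })
  }

  # --- methylation -> lung function linear models ---------------------------
  stage("methylation models", {
    zcols <- paste0("z_", config$outcomes)
    write_cohort(methylation_effect_table(analysis, outcomes = zcols),
                 file.path(out, "methylation_models.csv"))
    strat <- do.call(rbind, c(lapply(zcols, function(z) {
      stratified_and_interaction(analysis, z)
    }), list(make.row.names = FALSE)))
    write_cohort(strat, file.path(out, "methylation_stratified.csv"))
  })

  # --- manifest -------------------------------------------------------------
  files <- list.files(out, recursive = TRUE)
  files <- setdiff(files, c("manifest.csv", "log.txt"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out, files))),
    bytes = file.size(file.path(out, files))
  )
  utils::write.csv(manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE)
  logmsg("wrote %d artifacts", nrow(manifest))
  invisible(list(manifest = manifest, comparisons = comparisons,
                 reports = reports, out_dir = out))
}
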