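# bdlimwin

Sensitive-window analysis for prenatal air-pollution exposure: Bayesian
distributed lag interaction models (BDLIM) linking *weekly* gestational
PM2.5 to childhood lung-function z-scores and nasal GSTP1 promoter
methylation, with sex-specific timing and magnitude.

## Who this is for

Environmental epidemiologists and biostatisticians who have (or want to
simulate) a pregnancy cohort with weekly exposure histories and
early-childhood outcomes, and who want to answer: *during which
gestational weeks does exposure matter, does the window or its magnitude
differ by child sex, and is an epigenetic mark on the same pathway?*

## The model

For child *i* with covariates *z*, sex *g(i)*, and weekly exposures
*x*₁…*x*₄₀:

```
y_i = z_i'γ + β_{g(i)} Σ_t w_{g(i),t} x_{i,t} + ε_i,   ε_i ~ N(0, σ²),
‖w_g‖₂ = 1,  Σ_t w_{g,t} ≥ 0.
```

The distributed lag function δ_{g,t} = β_g·w_{g,t} factors into a
normalized weight function (timing → the sensitive window) and a scalar
within-window effect (magnitude). Weights live in a natural cubic spline
basis over the week grid. Four patterns — shared/shared (`n`),
shared weights/sex effects (`b`), sex weights/shared effect (`w`), both
sex-specific (`bw`) — are fit by a collapsed Metropolis-within-Gibbs
sampler and compared by DIC. A *sensitive window* is a maximal run of
weeks whose pointwise 95% credible interval for δ_{g,t} excludes zero;
the *cumulative effect* CE = Σ_t δ_{g,t} is the outcome change per
1 µg/m³ sustained across pregnancy.

Around the core model the package provides regression-based spirometry
z-scores, %5mC summaries with fourth-quartile dichotomization, the
adjusted linear models for methylation→lung-function (staged adjustment
sets, sex strata, interaction test), a calibrated synthetic-cohort
generator with known truth, and an end-to-end pipeline
(`run_pipeline()`) that writes every table, fit archive and figure with
a checksummed manifest.

## Worked example

Simulate a cohort of 800 children in which *only boys* carry a true
window at weeks 35–40 with cumulative effect −0.10 z-scores per µg/m³,
then ask the model which interaction pattern the data support and where
the window is:

```r
library(bdlimwin)

spec  <- truth_spec(n_children = 800, seed = 2)
delta <- calibrate_lag_truth(spec, "fev1", 35:40, -0.10)  # z -> raw scale
truth <- spec$true_lag_effects
truth$fev1$boy <- as.numeric(delta)
spec  <- truth_spec(n_children = 800, true_lag_effects = truth, seed = 2)

sim <- simulate_cohort(spec)
z   <- compute_lung_zscores(sim$cohort)
Z   <- model.matrix(~ maternal_age + maternal_education, sim$cohort)

fits <- lapply(c(n = "n", b = "b", w = "w", bw = "bw"), function(p)
  fit_bdlim(z$scores$z_fev1, sim$exposures, Z, group = sim$cohort$sex,
            spec = bdlim_spec(pattern = p, iter = 8000, burnin = 4000,
                              thin = 5, seed = 10)))
compare_patterns(fits)
#>   pattern      dic        pd delta_dic      weight  best
#> 1       n 2227.887  7.209595 10.300451 0.003949841 FALSE
#> 2       b 2219.741  7.783258  2.154246 0.232009375 FALSE
#> 3       w 2221.801 10.599326  4.214697 0.082810299 FALSE
#> 4      bw 2217.587  7.847387  0.000000 0.681230484  TRUE

window_report(fits$bw, level = 0.95)
#> <window_report> pattern 'bw', 95% pointwise intervals
#>   girl: windows none; CE -0.013 (-0.105, 0.047)
#>   boy: windows 31-40; CE -0.053 (-0.134, -0.002)
```

The both-differ pattern wins (normalized DIC weight 0.68, read as an
approximate probability that this is the best-fitting pattern of effect
modification). Boys show a late-pregnancy window overlapping the true
weeks 35–40 with a negative cumulative effect whose interval excludes
zero; girls show neither — the injected sex-specific truth, recovered.
At this single-cohort size the CE point estimate is noisy (the test
suite shows the median across 20 cohorts centers on −0.10).

The methylation arm works on the same table:

```r
meth <- summarize_gstp1(sim$cohort[, grep("^gstp1_s", names(sim$cohort))])
d <- cbind(sim$cohort, z$scores)
d$high_methylation <- dichotomize_top_quartile(meth$mean_5mC)$high_methylation
fit_adjusted_lm(d, "z_fev1", "M1")   # adjusted for maternal age + education
#>   outcome model_id stratum             term estimate     se p_value   n
#> 1  z_fev1       M1     all high_methylation  -0.0385 0.0802   0.631 800
```

(No methylation→FEV1 effect was injected here, and none is found.)

## Layout

- `R/` — generator (`truth_spec`, `simulate_cohort`), preprocessing
  (`compute_lung_zscores`, `summarize_gstp1`, `dichotomize_top_quartile`,
  `daily_to_weekly`), model (`fit_bdlim`, `compute_dic`,
  `compare_patterns`, `select_weight_df`), reporting (`window_report`,
  `cumulative_effect`, `plot_lag_curves`), methylation models
  (`fit_adjusted_lm`, `stratified_and_interaction`), pipeline
  (`pipeline_config`, `run_pipeline`).
- `vignettes/sensitive-windows.Rmd` — the methods vignette: model,
  priors, sampler, design decisions, generator calibration, limitations.
- `tests/testthat/` — unit, property and acceptance tests against
  independent oracles.
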