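---
title: "Identifying sensitive gestational windows with distributed lag interaction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying sensitive gestational windows with distributed lag interaction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Fetal lung development is a tightly scheduled program: airway branching,
saccular expansion, and the onset of alveolarization each occupy particular
spans of gestation. If an exposure such as fine particulate matter (PM2.5)
interferes with one of these processes, its effect on childhood lung
function should depend on *when* during pregnancy the exposure occurred,
not only on how much of it accumulated. Trimester averages blur this
timing; a weekly exposure history lets the data locate the vulnerable
span. Two further features of this problem motivate the package: effects
of prenatal exposures are often sex-specific (male fetuses appear more
vulnerable to oxidative stressors), and epigenetic marks such as promoter
methylation of *GSTP1* — a detoxification gene expressed in airway
epithelium — are candidate intermediates between exposure and function.

`bdlimwin` provides the full analysis chain for this setting: a Bayesian
distributed lag interaction model (BDLIM) relating weekly prenatal PM2.5
to childhood spirometry z-scores and to nasal-epithelium GSTP1 percent
methylation, pattern comparison for sex interaction, pointwise
credible-interval window identification, cumulative effects, the
downstream methylation-to-lung-function regressions, and a calibrated
synthetic-cohort generator so every stage is testable with known truth.

## The model

For child $i$ with covariates $z_i$, weekly exposures
$x_{i,1},\dots,x_{i,T}$ ($T = 40$ gestational weeks) and sex
$g(i) \in \{\text{girl}, \text{boy}\}$,

$$
y_i = z_i^\top\gamma + \beta_{g(i)} \sum_{t=1}^{T} w_{g(i),t}\, x_{i,t}
  + \varepsilon_i,\qquad \varepsilon_i \sim N(0,\sigma^2),
$$

with $\lVert w_g \rVert_2 = 1$. The distributed lag function
$\delta_{g,t} = \beta_g w_{g,t}$ is thus factored into a *timing*
component (the normalized weight function $w_g$, which identifies the
sensitive window) and a *magnitude* component (the scalar within-window
effect $\beta_g$). Four interaction patterns express which components the
sexes share:

| pattern | weights | effects |
|---|---|---|
| `n`  | shared | shared |
| `b`  | shared | sex-specific |
| `w`  | sex-specific | shared |
| `bw` | sex-specific | sex-specific |

Each weight vector is constrained to the span of a natural cubic spline
basis over the week grid ($K$ columns, interior knots evenly spaced;
`build_weight_basis()`), which smooths the weekly weights and reduces the
effective dimension. The default $K = 5$ places roughly one knot per
eight weeks; `select_weight_df()` implements the usual practice of
choosing $K$ by DIC. Sharp or narrow features need a finer basis — in our
validation studies an 11-week bump is resolved well at $K = 9$ but is
visibly distorted at $K = 5$, and the DIC search makes that choice
data-driven.

### Priors and identification

* $(\gamma, \beta)$ jointly $N(0, c^2\sigma^2 I)$ with $c^2 = 100$:
  weakly informative on standardized outcomes. Scaling the prior by
  $\sigma^2$ makes the regression block exactly conjugate
  (normal-inverse-gamma), which gives the sampler an analytically
  verifiable limit (see *Validation* below).
* $\sigma^2 \sim \text{Inverse-Gamma}(0.01, 0.01)$.
* Spline coefficients $\xi_g$ ($w_g = B\xi_g / \lVert B\xi_g\rVert$) have
  a standard normal prior restricted to the half-space
  $\sum_t w_{g,t} \ge 0$. The pair $(\beta_g, w_g)$ is invariant to a
  joint sign flip, so a convention is required; the half-space constraint
  enforces it for *every* draw exactly. A post-hoc flip would not suffice
  under pattern `w`, where the two sexes share $\beta$ and flipping one
  group's weights alone is not a likelihood symmetry.

### Computation

The sampler alternates (i) a random-walk Metropolis update of each
$\xi_g$ on the *marginal* likelihood with $(\gamma,\beta,\sigma^2)$
integrated out (possible because of conjugacy), and (ii) an exact joint
draw of $(\sigma^2,\gamma,\beta)$ given the weights. Collapsing the
regression block matters: with it, a proposed window shape is evaluated
with the effect size instantly adapted, which removes the pathological
coupling between weight shape and effect magnitude that slows an
uncollapsed sampler. Two further numerical choices:

* Exposure columns are centered internally whenever the covariate design
  spans a constant. This is a pure reparametrization of the intercept,
  but without it the weight update must drag the intercept along and
  mixing collapses.
* Proposals mix a local step (scale adapted during burn-in toward 20–40%
  acceptance, then frozen) with an occasional five-fold step to cross
  between weight-shape modes. Chains start at the unconstrained
  distributed-lag least-squares solution projected into the basis.

Defaults are 10,000 iterations, 5,000 burn-in, thinning 5, all recorded
in the fit together with the seed. Effective sample sizes of the
$\beta_g$ are reported and a fit is flagged (not errored) when one falls
below 100.

## Model comparison and reported quantities

`compute_dic()` uses the classic decomposition
$\bar D = E[-2\log L]$, $p_D = \bar D - D(\hat\theta)$,
$\mathrm{DIC} = \bar D + p_D$, evaluating $D(\hat\theta)$ at posterior
means with each averaged weight vector renormalized.
`compare_patterns()` converts DIC differences into normalized weights
$\propto \exp(-\Delta\mathrm{DIC}/2)$. These are DIC-based
pseudo-probabilities, labelled as such in the output metadata; they are
an operational stand-in for a model probability, not a marginal
likelihood.

`window_report()` summarizes $\delta_{g,t}$ draws by their pointwise
equal-tailed credible interval per week; a *sensitive window* is a
maximal run of consecutive weeks whose interval excludes zero, reported
as a closed integer range (e.g. 35–40). Equal-tailed percentile
intervals, not HPD, match the usual shaded-band display and need no
density estimation; bands are pointwise by design, so weeks are
interpreted marginally. The *cumulative effect*
$\mathrm{CE}_g = \sum_t \delta_{g,t} = \beta_g \sum_t w_{g,t}$ is
computed draw by draw — an identity the test suite asserts exactly.

## Preprocessing conventions

* **Spirometry z-scores** (`compute_lung_zscores()`): each raw outcome
  (FEV1, FVC, FEV1/FVC, FEF25–75) is regressed on child age, sex, height
  and race/ethnicity; residuals are divided by their sample SD. This is
  internal-cohort standardization — the four z-columns have mean 0 and SD
  1 in the analysis sample by construction — not a published reference
  equation. Coefficients and residual SDs are retained so new children
  can be scored on the same scale. The ratio is standardized with the
  same covariate set as the other outcomes.
* **Methylation** (`percent_methylation()`, `summarize_gstp1()`):
  %5mC is 100·methylated/(methylated+unmethylated) per CpG; the child
  -level value is the arithmetic mean over the 17 assayed sites
  (non-missing sites only, with the missing count reported). Whether a
  published "percent methylation" refers to the panel mean or a single
  position is often ambiguous; the mean is the default here and
  site-level columns are kept so any alternative summary can be formed.
* **Top-quartile dichotomization** (`dichotomize_top_quartile()`): the
  high-methylation group is defined by the sample 75th percentile under
  the type-7 (linear interpolation) quantile rule, declared in the
  output. With the default generator calibration the threshold sits near
  3.0 %5mC, splitting off about a quarter of children.
* **Daily aggregation** (`daily_to_weekly()`): week $t$ averages
  gestational days $7(t-1)+1$ to $7t$; a trailing partial week is
  averaged over its available days rather than dropped, because the
  delivery week is precisely where late-pregnancy windows live; weeks
  with no days are flagged missing.

## The synthetic cohort generator

No individual-level cohort of this kind is publicly deposited, so the
package ships a generator (`truth_spec()`, `simulate_cohort()`) whose
*marginal* summaries are calibrated to the descriptive statistics of an
urban full-term pregnancy cohort, and whose *true* lag effects are known
inputs:

* **Exposure**: weekly PM2.5 is mean 10.9 µg/m³ plus an annual sinusoid
  (amplitude 3 µg/m³, uniform random conception phase) plus AR(1) noise
  ($\rho = 0.7$, innovation SD 1.5 µg/m³), truncated at zero. At these
  values the per-subject pregnancy average has median ≈ 10.9 and IQR
  ≈ 10.2–11.6 µg/m³. The real exposure surface comes from a hybrid
  satellite/land-use model that is out of scope; only these marginals and
  a realistic autocorrelation are emulated.
* **Covariates**: boys 52.1%; Black/Hispanic/White-other 22.8/65.5/11.7%;
  maternal education ≤12y 66.7%; never/prenatal-only/postnatal-only/both
  smoking 71.4/8.2/14.0/6.4%; asthma 15.8%; child age ~N(6.9, 0.8) yr;
  maternal age ~N(27.2, 5.7) yr; height linear in age (6 cm/yr, SD 5 cm)
  to create the collinearity the z-score stage must handle; gestational
  age uniform on 37–41 completed weeks (a full-term sample), while the
  exposure matrix always carries 40 columns — ambient concentrations
  exist regardless of delivery date.
* **Spirometry**: FVC and FEF25–75 follow linear models whose
  age/sex/height/race component is an exact linear function of the
  z-score covariates; FEV1 is built as (latent ratio)·FVC with the ratio
  truncated at 1, so `fev1 <= fvc` and `fev1_fvc = fev1/fvc` hold by
  construction. Marginal means/SDs land near 1.44 (0.25) L for FEV1,
  1.58 (0.29) L for FVC, 0.92 (0.05) for the ratio and 1.87 (0.46) L/s
  for FEF25–75.
* **Methylation**: the child-level GSTP1 value is lognormal. Three
  printed quantiles (median 2.26, quartiles 1.56 and 3.02) over-determine
  the two lognormal parameters; the package fixes the median exactly
  (meanlog = log 2.26) and balances the two quartile errors
  (sdlog = 0.47087, both quartile errors ≈ 0.085). The 17 site values are
  scaled lognormal multipliers normalized to preserve the child-level
  mean exactly.
* **True lag effects** $\delta^*_{g,t}$ enter the raw outcome with
  coefficient exactly one (raw units per µg/m³) — with noise switched off
  two children differing by 1 µg/m³ in one week differ in outcome by
  exactly $\delta^*$. Because the analysis is run on z-scores, the helper
  `calibrate_lag_truth()` converts a target z-scale cumulative effect to
  the raw scale using the residual SD of a large internally generated
  null reference cohort (fixed internal seed, so the conversion is a pure
  function of the spec).

Every generator is a pure function of the spec, including its seed.

### What the generator does and does not emulate

It reproduces marginal distributions, realistic covariate collinearity
and temporal autocorrelation of exposure. It does **not** reproduce
spatial structure, residential mobility, exposure-model error, assay
noise correlated across CpGs with biological structure, or outcome
non-linearity. Passing recovery tests therefore demonstrates that the
estimation machinery is correct under its assumed data-generating
process, not that the scientific findings would replicate in new data.

One property of the chosen exposure process deserves emphasis. A shared
annual sinusoid with random phase makes exposures about 26 weeks apart
strongly *anti*-correlated, so a late-pregnancy window can be partially
mimicked by an opposite-signed mid-pregnancy component ("seasonal
mirroring"). The week-resolved window is still identified through the
AR(1) innovations, but the cumulative effect is information-limited: at
500 children per sex the unrestricted distributed-lag OLS has a CE
standard error near 0.06 z-units per µg/m³, and the BDLIM posterior
tracks it. Our recovery study therefore evaluates the *median* CE across
20 simulated cohorts, which is what a method-property claim should rest
on. Real exposure series share this confounding (season is a classic
confounder of air-pollution studies), which is why window methods are
usually read for timing rather than for precise cumulative magnitudes.

## Validation design

The test suite checks the machinery against independent oracles rather
than against itself:

* With weights held fixed the model is a normal-inverse-gamma linear
  regression; the sampler's posterior means and its DIC are compared to
  exact closed forms (and to ordinary least squares) within Monte Carlo
  error.
* All least-squares stages (z-scores, methylation models) are compared
  to an independently coded normal-equations solver at 1e-8.
* The spline basis is compared, via orthogonal projections, to a
  truncated-power construction of the natural cubic spline space.
* Recovery studies: 20 cohorts of 500 boys + 500 girls with a boys-only
  window at weeks 35–40 (cumulative effect −0.10 z per µg/m³) are fit
  with pattern `bw`; medians of the sex-specific CEs, window hit rates
  and null-calibration of the pointwise bands are asserted. Pattern
  selection is checked under a both-differ truth with mirror-separated
  windows (boys 33–40, girls 15–25) and under a shared truth.

Problem sizes (n = 300–1,000 children, 4,000–8,000 MCMC iterations,
10–20 replicates per claim) are chosen so the whole suite runs in a few
minutes while keeping the Monte Carlo error of each asserted summary an
order of magnitude below its tolerance.

## Known limitations

* Binary effect modifier only (two groups), Gaussian outcomes only.
* Pointwise (not simultaneous) credible bands; windows inherit their
  multiplicity behaviour.
* DIC pseudo-probabilities approximate — they are not posterior model
  probabilities.
* The normalized weight function makes $\beta_g$ interpretable only
  jointly with $w_g$; report $\delta_{g,t}$ and CE, not $\beta_g$ alone.
* Formal mediation of the exposure–methylation–function pathway is out
  of scope; the package fits the association models on either side.
* PDF figures embed creation timestamps; the pipeline's byte-level
  determinism guarantee covers its data artifacts (runs intended to be
  byte-identical should disable figures).
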