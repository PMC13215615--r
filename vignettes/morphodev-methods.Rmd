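---
title: "Methods: multi-site morphometry harmonization, normative deviations and leakage-safe classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-site morphometry harmonization, normative deviations and leakage-safe classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodev)
```

## Scope

`morphodev` implements three complementary analyses of regional brain
morphometry pooled across imaging sites in a case-control design
(anorexia nervosa, AN, versus healthy controls, HC, with restricting
(AN-R) and binge-eating/purging (AN-BP) subtypes):

1. a **mega-analysis**: per-metric general linear models on
   site-harmonized data with covariate-adjusted Cohen's *d* and
   Benjamini–Hochberg FDR;
2. a **normative-deviation analysis**: per-participant z-scores against a
   normative reference model, exact binomial tests of extreme-deviation
   frequencies, subtype proportion comparisons, and bootstrap-tested
   heterogeneity indices;
3. a **leakage-safe classification pipeline**: confound regression, PCA
   and a class-weighted linear SVM inside stratified nested 10-fold
   cross-validation with in-fold ComBat-GAM, plus leave-site-out
   evaluation without harmonization.

Because no participant-level consortium data can be shipped, a
**synthetic cohort generator** provides the stated world in which the
package is calibrated and tested. It is first-class, tested code, not a
fixture.

## The synthetic cohort: what it emulates, and what it does not

Each metric $v$ with base residual SD $\sigma_v$ is generated as

$$ y_{iv} = \mu_v + f_{\mathrm{fam}}(a_i) + d_v\,\sigma_v\,[g_i=\mathrm{AN}]
   + s_{\mathrm{site}(i)}\sigma_v + \lambda\,\sigma_v\,z(\mathrm{ICV}_i)
   + c_{\mathrm{site}(i)}\,\kappa^{[g_i=\mathrm{AN}]}\,\sigma_v\,\varepsilon_{iv} $$

with $\varepsilon_{iv}\sim N(0,1)$ independent across metrics. Defaults
are the reported characteristics of the multi-site case-control
cohort this generator emulates, wherever one is available:

* **Layout**: 11 sites, 570 AN (417 AN-R, 135 AN-BP, 18 unlabelled) and
  739 HC, split unevenly across sites (exact per-site splits are not
  public; the uneven default split is an assumption).
* **Demographics**: AN BMI 15.49 (1.54) kg/m², HC 21.33 (2.20); AN-BP on
  average older (+2.5 y) and heavier (16.2 vs 15.3 kg/m²) than AN-R.
  Site age means span 16.5–26 years.
* **Effect sizes**: per-metric Cohen's $d_v$ drawn once (fixed internal
  seed) so family means and SDs are exact — CT $-0.54\,(0.22)$, SA
  $-0.23\,(0.07)$, SV structures $-0.37\,(0.13)$ — with positive
  exceptions for the left temporal pole ($+0.15$), right entorhinal
  cortex ($+0.13$) and lateral ventricles ($+0.30$).
* **Heterogeneity**: AN residual SD inflated by $\kappa = 1.3$, the
  variance-heterogeneity signature the deviation analyses target.
* **Age**: CT declines piecewise-linearly after age 8
  ($-0.02\,\sigma$/year); SA/SV are flat in age. Any smooth non-trivial
  shape suffices to exercise the spline machinery; this one was chosen
  for simplicity and monotonicity.
* **Head size**: ICV loads on SA/SV metrics with $\lambda = 0.6$,
  giving a marginal correlation near 0.5 (mid "0.3–0.7" range).
* **Subtypes carry zero true brain effect**, so every subtype analysis
  is null by construction and the package's null behaviour is testable.

One deliberate consequence of the generating equation: with
$\kappa > 1$ the *population pooled-SD Cohen's d* is attenuated relative
to the injected $d_v$ by $\sqrt{f\kappa^2 + (1-f)} \approx 1.14$ ($f$
the AN fraction). We inject on the base-SD scale because that is how the
generative model is stated; recovery tests account for the attenuation
being partially offset by significance selection.

The generator does **not** emulate: non-Gaussian residuals, between-metric
residual correlation beyond the shared ICV/global factors, scanner
software or field-strength structure within site, longitudinal change, or
covariate-dependent missingness (masking is uniform at a configurable
rate, emulating segmentation QC removals). A green test therefore
establishes algorithmic correctness and statistical calibration in this
stated world, not clinical validity on real consortium data; the
headline numbers reported for the real consortium (e.g. ROC-AUC 0.81,
61 significant CT regions, deviation thresholds near 4%) depend on that
data and are used only as calibration targets and direction checks.

## ComBat-GAM harmonization

Per metric: an OLS model with one indicator per site plus the retained
covariates — a cubic B-spline in age with 5 interior knots at training
quantiles (the smooth term), linear BMI and ICV, and the diagnosis or
subtype factor — is fitted; residuals are standardized by the pooled
residual SD; per-site location ($\gamma$) and scale ($\delta$) of the
standardized data are estimated and shrunk by empirical Bayes (normal
prior on $\gamma$, inverse-gamma on $\delta^2$), iterating the
conditional posterior means to $10^{-6}$ or 100 iterations.

Choices a maintainer should know:

* **Hyperparameters pool across metrics.** A prior cannot be estimated
  from a single metric; as in reference implementations, the
  method-of-moments hyperparameters for each site pool over all metrics
  being harmonized. Site location/scale remain per metric.
* **Spline basis**: cubic B-spline, 5 interior knots at age quantiles,
  clamped at the training boundary for new data. The underlying GAM
  reference does not pin a basis; this one is smooth and stable at fold
  sizes of a few hundred.
* **Fit/apply separation**: `apply_combat_gam()` uses only stored
  parameters, so it can transform held-out rows of known sites without
  leakage; unknown sites are an error by contract (leave-site-out
  pipelines therefore omit harmonization).
* **Degenerate cells**: sites contributing fewer than 3 usable values to
  a metric are excluded from EB for that metric (identity adjustment,
  warning); single-site input yields the identity; a metric column also
  serving as a covariate is not harmonized.
* **`eb = FALSE`** disables shrinkage and exists so the two-batch
  closed-form oracle (standardize–centre–rescale) can be checked exactly.

## Mega-analysis

The covariate policy is a pure function of contrast and family: age and
age² always (age mean-centred before squaring to limit collinearity);
BMI only in AN-R vs AN-BP (a severity proxy, not a subtype trait); ICV
only for SA and SV. The group *t* is converted to Cohen's *d* via
$d = t\,(n_1+n_2)/(\sqrt{n_1 n_2}\sqrt{\mathrm{df}})$ — the standard
conversion for covariate-adjusted two-group GLMs; the reported-style CI is
normal-based with $\mathrm{SE}(d) = \sqrt{(n_1+n_2)/(n_1 n_2) +
d^2/(2\,\mathrm{df})}$ (whether the original CIs were t- or normal-based
is unstated; normal was assumed). FDR is applied within family (CT, SA,
SV), matching the per-panel presentation convention; a pooled switch
exists.

## Normative deviations

The normative model is a deliberately simple stand-in for a pretrained
centile model whose weights are not available: per metric, spline(age)
plus the family's global covariate (mean CT for CT, total SA for SA, ICV
for SV), homoscedastic residual SD, fitted on a large synthetic healthy
reference (ages 5–90, female-only by construction of the cohort).
Consequences that the tests make explicit:

* z-scoring held-out reference data gives per-tail extreme rates of 2.5%
  (the ±1.96 thresholds are strict inequalities; z = 1.96 is "normal");
* because the global covariate absorbs global shifts, a uniform CT
  deficit leaves regional z-rates normative — a regional extreme is a
  deviation *given* global brain structure, not an absolute one;
* the exceedance null is an exact one-sided binomial at $p_0 = 0.025$
  per tail (the original appendix specifying this is unavailable; this
  is an interpretive reconstruction), with BH-FDR within family × tail;
  the reported per-family "threshold" is the smallest significant
  percentage;
* subtype proportions use the pooled two-proportion z without continuity
  correction;
* heterogeneity indices (mean over metrics of the SD of z across
  participants) are tested by resampling participants with replacement
  from the reference deviation table, size-matched, 1000 draws by
  default.

## Classification

Pipeline order: in-fold ComBat-GAM (nested CV only) → per-feature linear
confound regression (age; BMI for the subtype task; ICV additionally for
SA/SV features) with train-only coefficients → train-mean imputation →
standardization → PCA → class-weighted linear SVM. Decisions:

* **SVM**: L2-regularized squared-hinge primal, inverse-class-frequency
  weights, deterministic BFGS from zero initialization; the risk score is
  the signed distance to the hyperplane. No SVM library meeting the
  determinism and weighting requirements is available in the target
  environment, so the solver is in-package and oracle-tested against a
  least-squares direction on separable data.
* **Grids**: PCA components {10, 20, 40, 80, all} and cost
  {0.01, 0.1, 1, 10} (the original grid table is unavailable); both are
  configurable, ties break to the first grid point deterministically.
* **Stratification**: folds stratified by class within site.
* **PR-AUC** (average precision, tie-blocked — a constant scorer scores
  exactly the prevalence) is the optimization metric; ROC-AUC is
  reported for cross-task comparability, pooled over concatenated
  held-out scores.
* **Permutations** respect the site structure (labels permuted within
  site); `p = (1 + \#\{perm \ge obs\})/(1 + B)`. Inside `run_study()`
  permutation re-runs fix the hyperparameters to the modal outer-fold
  choice of the observed run — under permuted labels the grid search
  selects among equally uninformative models, so the null is unchanged
  while runtime drops by the grid factor.
* **Feature importances** are forward-model (Haufe) correlations between
  each feature and the held-out risk score, with a score-permutation
  null and BH-FDR.
* **Confound deviance**: logistic deviance decomposition
  `(D_confounds − D_full)/D_confounds`, permuting scores within
  confound strata (quantile bins of the confound-only linear predictor);
  separation triggers a ridge-penalized refit with a warning.
* The neural-network backend is an extension point only; reported
  comparisons found no performance difference over the linear SVM for
  this problem.

## Numerical and degenerate-input policy

Missing metric cells are `NA` (never 0), complete-case fitted, and
excluded from per-metric sample sizes; constant metrics and
perfectly-predicted normative metrics are errors; constant confounds are
dropped with a warning; empty tables pass through harmonization; a
held-out site with one class reports fold AUCs as `NA` with a message
while still contributing pooled scores. All randomness flows from one
top-level seed through `child_seed(seed, stage)`, so every pipeline is
bit-reproducible.

## Known limitations

Metrics are conditionally independent in the generator, which makes
multivariate classification easier than on real data at matched effect
sizes; the normative model is homoscedastic whereas real centile models
are not; harmonization of a site requires its presence at fit time; no
vertex-wise or longitudinal analysis. Every quantitative claim above is
recomputed by the test suite or `scripts/acceptance.R`; the vignette
itself states no number the code does not produce.
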