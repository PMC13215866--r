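---
title: "Measuring health poverty vulnerability: models, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring health poverty vulnerability: models, conventions, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vepvuln)
```

## The problem

Poverty headcounts are ex-post: they tell you who is poor now. For health
policy, the more useful quantity is ex-ante: which households have a high
probability of falling below the poverty line in the future because a health
shock drains income or triggers medical spending. `vepvuln` operationalizes
this as *vulnerability as expected poverty* (VEP), estimable from a single
cross-section, and couples it with two downstream analyses: heterogeneity of
covariate effects across the vulnerability distribution (quantile
regression), and a construct-level path model of how livelihood capitals and
medical-services utilization transmit to vulnerability.

## The VEP model and the three-stage FGLS estimator

We assume future log per-capita income is conditionally normal,

$$\ln Y_h \mid X_h \sim \mathcal N(X_h\beta,\; X_h\theta),$$

with both the mean and the variance linear in household covariates
(demographics, chronic-illness status, institutional protection). The
estimator (`fit_income_fgls()`) is the classic three-stage FGLS sequence:
OLS for the mean; OLS of squared residuals for the variance function; then
weighted re-estimation of the variance and mean equations, each weighted by
the inverse fitted variance. Given $\hat\beta,\hat\theta$ and a poverty line
$l$, the vulnerability index (`vulnerability_index()`) is

$$v_h = \Pr(\ln Y_h \le \ln l \mid X_h)
      = \Phi\!\left(\frac{\ln l - X_h\hat\beta}{\sqrt{X_h\hat\theta}}\right),$$

and a household is classified high-vulnerability when $v_h \ge 0.5$
(configurable). The z-score denominator is the *square root* of the fitted
variance — the only form under which $\Phi$'s argument is a z-score; we note
this explicitly because the linear variance specification is sometimes
typeset ambiguously in applied work.

Numerical conventions:

* **Variance flooring.** Regressing squared residuals linearly can produce
  negative fitted variances. Fitted variances are floored at `eps = 1e-6`;
  floored rows are flagged and counted, never silently repaired. The stage-3
  weighting kernel is `1/max(h, eps)` by default, with `|h|` and `h²`
  variants available, since the literature names the procedure but not the
  kernel.
* **Log conventions.** Income must be strictly positive; rows violating this
  are excluded with a logged count (mirroring listwise deletion in survey
  practice). Expense-style covariates with mass at zero should be supplied
  as `log(x + 1)` — the synthetic generator follows that convention.
* **Exact OLS collapse.** With an intercept-only variance design the FGLS
  weights are exactly constant and $\hat\beta$ equals OLS to machine
  precision; with covariates in the variance design the fitted weights vary
  by $O(n^{-1/2})$ even under true homoscedasticity, so only approximate
  agreement can be (and is) asserted.

Supporting utilities: the prevalence sample-size formula
$N = \lceil u_\alpha^2\,\pi(1-\pi)/\delta^2\rceil$
(`compute_min_sample_size()`; at $\pi = 0.5$, $\delta = 0.05$, $u = 1.96$ it
gives 385), the relative poverty line as a fraction of per-capita disposable
income with a recorded rounding mode, survey-style tabulation with half-up
two-decimal percentages, and the distribution summary with left-closed bins
and a closed top bin (an index of exactly 1 belongs to the top bin).

## Quantile heterogeneity

The vulnerability index (bounded in $[0,1]$, typically bimodal) is regressed
on resource-endowment and utilization covariates at $\tau = 0.25, 0.50,
0.75$ — low, moderate and high vulnerability. The index is regressed on its
raw scale (no logit transform), matching common applied practice.

* **Solver.** `fit_quantile()` minimizes the check loss exactly with a
  vertex-exchange (exterior-point) algorithm: an optimal solution
  interpolates $p$ observations; the solver walks between such basic
  solutions along directions of negative one-sided derivative, taking exact
  piecewise-linear line-search steps. Its objective is verified against a
  brute-force enumeration of all interpolating fits for small problems.
  Residuals within `1e-9·(1 + mean|y|)` of zero are treated as ties
  (bootstrap resamples duplicate rows; without this the exchange step length
  collapses and the algorithm cycles). Resamples that lose a rare indicator
  entirely (rank-deficient design) are dropped from the bootstrap with a
  warning rather than aborting the analysis.
* **Standard errors and Wald tests.** All standard errors are paired
  (row-resampling) bootstrap with recorded seed and replication count. The
  same set of resamples is fitted at every $\tau$, giving the joint
  covariance of stacked coefficients needed by the cross-quantile Wald tests
  (`cross_quantile_tests()`): per variable, a joint test of equality across
  the three quantiles (2 df) and pairwise tests of adjacent differences.
  Simultaneous-quantile analytic covariances (as in some commercial
  software) are deliberately not reproduced; the bootstrap is the documented
  stand-in, and its size is verified by a null-calibration simulation.
* **Shape labels.** `classify_pattern()` is a pure function of the three
  coefficients and the two pairwise significance flags: inverted-V when the
  middle coefficient is the strict maximum (V when strict minimum) with both
  flags set; `monotone` for strict ordering with both flags; ties and
  everything else are `flat/other`. A `lenient` rule accepting the peak
  ordering without significance is available because published tables
  sometimes label a peak shape even when one pairwise step is insignificant;
  the strict rule is the default.
* Significance is fixed at 0.05 with no multiple-testing correction by
  default (a Bonferroni option exists), matching the applied convention the
  package mirrors.

Subgroup analysis (`subgroup_equality()`) fits the full model per group and
tests per-variable equality with $(b_A-b_B)^2/(SE_A^2+SE_B^2) \sim
\chi^2_1$; `fit_interactions()` appends product terms instead. A
`full_quantile_sweep()` exports tidy coefficient curves over a $\tau$ grid.

## Composite path model

Latent-variable SEM with formative indicators requires weights and
identification choices that published applied work rarely reports. The
package therefore uses **composite-score path analysis**: each construct is
the mean of its sign-aligned z-scored indicators, re-standardized
(`build_composites()`). Every downstream number is then deterministic and
testable. The cost is deliberate: composite coefficients are attenuated
relative to latent-variable loadings, so exact reproduction of
latent-model coefficient tables is out of scope — what is reproducible, and
what the acceptance targets check, is the *decomposition arithmetic* from
published coefficients.

For the acyclic construct diagram (human → physical → social; human →
utilization; all four → vulnerability), each endogenous construct is
regressed on its parents — on standardized data this is the ML solution of
the recursive system with uncorrelated errors. Effects decompose through the
direct-coefficient matrix $B$:

$$T = (I - B)^{-1} - I, \qquad \text{indirect} = T - B,$$

equal to the sum over all directed multi-edge paths of edge-coefficient
products (property-tested against explicit path enumeration on random
DAGs). The implied covariance is $\Sigma = (I-B)^{-1}\Psi(I-B)^{-\top}$, and
`fit_indices()` computes χ² from the ML discrepancy plus GFI, AGFI, PGFI,
IFI, CFI, SRMR (RMS of standardized residuals over the lower triangle
including the diagonal) and RMSEA. Discrepancies at machine-precision level
are clamped to zero so a saturated model reports exactly χ² = 0. The default
utilization construct omits the outpatient out-of-pocket and
physical-examination indicators (the "modified model"); the full indicator
set is available via `default_construct_spec(modified = FALSE)`.
Modification-index-driven respecification is judgment-driven and
dataset-specific, and is not implemented; the diagram is user-supplied.

## The synthetic world

`generate_survey()` produces surveys with the exact structure the estimators
assume, so parameter recovery is a meaningful test:

* Construct scores follow the recursive DAG with configurable standardized
  coefficients; indicators attach to their construct through a Gaussian
  copula (loading ρ, default 0.3–0.65 per indicator), which makes every
  configured marginal **exact** while inducing the dependence structure.
* Marginals are calibrated to the published summary table of the study
  population (e.g. tap water 95.5%, chronic illness 69.3%, durable products
  ≈ Poisson(10.03), zero-inflated log cash gifts 6.44 ± 3.38). All are
  configurable.
* Log income is drawn from $\mathcal N(X\beta, X\theta)$. The construct →
  vulnerability links are realized through the income mean (a construct that
  raises vulnerability lowers expected log income, scale 0.8), so the
  published signs propagate. The default coefficients were chosen once so
  that, at the 9,202 CNY relative line, the simulated vulnerability
  distribution shows the broad shape reported for the study population:
  heavy outer bins and roughly 47–49% of households above the 0.5 threshold.
* The exact crossing probability of every household is returned as
  `true_vulnerability`; its mean equals the expected poverty headcount of a
  fresh income draw (tested within Monte-Carlo error).
* One master seed expands into labelled substreams per variable block
  (`substream_seed()`), so adding or disabling a block never perturbs
  another's draws; regeneration is bit-identical.

What the generator does **not** emulate — and therefore what a green test
does not establish: village-level clustering and spatial correlation;
item nonresponse; measurement error in self-reports; panel dynamics; the
latent-formative measurement structure of real capital constructs (the
generator's constructs are the copula factors themselves). Recovery tests
certify the estimators under their own assumptions, not the field validity
of the survey instrument.

A feasibility guard rejects configurations whose variance design can go
non-positive: offending rows are resampled up to a cap, then the
configuration is refused with the first offending row named.

## Design choices on open points

* The exact covariate list of the income equation is exposed as
  configuration (`income_model_spec`); defaults use household size,
  dependency ratio (Beta(2,3): dependents over household size), chronic
  illness, medical insurance and medical debt.
* The prevalence-formula worked value at the study's stated inputs is 981,
  not the sometimes-quoted "≈864" (which corresponds to a different absolute
  error); the formula is implemented as stated and 864 is not targeted.
* Headcounts are reported bin-consistently: the share above threshold is
  computed from the same vector as the bin counts, so the percentage and the
  counts can never disagree.
* Robustness poverty lines (e.g. a $/day standard) require a currency
  conversion that is context-dependent; the line is always a configuration
  scalar, never hard-coded.
* Reported percentages are rounded half-up to 2 decimals; effect tables are
  reported at 3 decimals alongside full precision.

## Known limitations

* Bootstrap SEs are approximations; at small n with rare binary covariates
  many resamples can be degenerate (they are dropped with a warning and the
  effective replication count shrinks).
* Composite path coefficients are attenuated relative to latent-variable
  analyses; standardized coefficients can exceed 1 in ill-conditioned
  composites and are flagged, not truncated.
* The vulnerability index enters the quantile stage untransformed; with
  boundary-heavy indices extreme-τ fits can be unstable (the default τ set
  avoids the boundary).
* No sampling weights or clustered variance corrections.
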