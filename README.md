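# vepvuln

Household **health poverty vulnerability** analysis in R: who is likely to be
poor *tomorrow* because of health shocks, even if they are not poor today?

`vepvuln` is aimed at health-economics and public-health researchers working
with cross-sectional household surveys (the kind collected in rural
development and health-system studies). It implements:

1. **Vulnerability as expected poverty (VEP)** via a three-stage feasible
   generalized least squares (FGLS) income model. Log per-capita income is
   modelled with covariate-dependent mean *and* variance,

   - stage 1: OLS of `ln Y` on `X` → residuals `e`
   - stage 2: OLS of `e²` on `X` → fitted variances `h = X θ_OLS`
   - stage 3: WLS of `e²` on `X` with weights `1/max(h, ε)` → `θ̂`
   - stage 4: WLS of `ln Y` on `X` with weights `1/max(X θ̂, ε)` → `β̂`

   and each household's vulnerability is the normal crossing probability

   `v = Φ( (ln l − X β̂) / √(X θ̂) )`

   for poverty line `l` (default: a relative line at 60% of per-capita
   disposable income). Households with `v ≥ 0.5` are classified
   high-vulnerability.

2. **Quantile-heterogeneity analysis** of the vulnerability index: an exact
   check-loss quantile-regression solver (vertex-exchange algorithm, compiled
   with Rcpp/RcppArmadillo), OLS baseline, VIF screening, paired-bootstrap
   cross-quantile Wald tests at τ = 0.25/0.50/0.75 with
   V / inverted-V / monotone shape labels, farming-subgroup equality tests,
   interaction models, and a full quantile sweep.

3. **Recursive path analysis** on standardized construct composites (human,
   physical, social capital; medical-services utilization; vulnerability):
   least-squares path coefficients with bootstrap standard errors,
   standardized **direct/indirect/total effect decomposition**
   (`total = (I − B)⁻¹ − I`), model-implied covariance and the covariance
   fit indices χ², GFI, AGFI, PGFI, IFI, CFI, SRMR, RMSEA.

4. A **seeded synthetic household-survey generator** whose defaults are
   calibrated to the published summary tables of a rural western-China
   middle-aged/older household survey, with exact ground-truth vulnerability
   for recovery testing.

## Worked example

```r
library(vepvuln)

cfg    <- synthetic_config(n_households = 4371, seed = 1)
survey <- generate_survey(cfg)

spec <- income_model_spec(
  c("household_size", "dependency_ratio", "health_status",
    "medical_insurance", "medical_debt"),
  c("dependency_ratio", "health_status", "medical_debt"))
fit  <- fit_income_fgls(survey$table, spec)
pred <- predict_mean_variance(fit, survey$table)
v    <- vulnerability_index(pred$mu, pred$sigma2, poverty_line = 9202)
classify_and_summarize(v)
#> Vulnerability distribution (n = 4371 )
#>          bin count percent  mean    sd
#>    [0, 0.25)   866   19.81 0.143 0.066
#>  [0.25, 0.5)  1618   37.02 0.378 0.070
#>  [0.5, 0.75)  1307   29.90 0.609 0.071
#>    [0.75, 1]   580   13.27 0.840 0.059
#> Households with index >= 0.50: 1887 (43.17%)
```

About 43% of the simulated households have an estimated probability ≥ 0.5 of
falling below the 9,202 CNY/person-year relative poverty line — the
"high vulnerability" group a monitoring system would flag.

Feeding published standardized path coefficients into the effect
decomposition reproduces a standardized-effects table:

```r
eff <- decompose_effects(data.frame(
  from = c("human","human","human","physical","physical","social","utilization"),
  to   = c("physical","utilization","vulnerability","social",
           "vulnerability","vulnerability","vulnerability"),
  estimate = c(0.733, -0.128, 0.415, 0.456, -0.433, -0.195, -0.035)),
  default_path_diagram())
eff
#>                          path direct indirect  total
#>             human -> physical  0.733    0.000  0.733
#>          human -> utilization -0.128    0.000 -0.128
#>               human -> social  0.000    0.334  0.334
#>        human -> vulnerability  0.415   -0.378  0.037
#>            physical -> social  0.456    0.000  0.456
#>     physical -> vulnerability -0.433   -0.089 -0.522
#>  utilization -> vulnerability -0.035    0.000 -0.035
#>       social -> vulnerability -0.195    0.000 -0.195
```

Physical capital's direct effect on vulnerability (−0.433) is amplified by an
indirect channel through social capital (0.456 × −0.195 ≈ −0.089), for a
total of −0.522: asset-building is the strongest protective lever in this
model.

## Command line

```sh
Rscript -e 'vepvuln::vepvuln_cli()' simulate --n 4371 --seed 1 --out survey.csv
Rscript -e 'vepvuln::vepvuln_cli()' vep --in survey.csv --line 9202 --threshold 0.5 --out vep.csv
Rscript -e 'vepvuln::vepvuln_cli()' quantiles --in survey.csv --taus 0.25,0.5,0.75 --boot 500 --seed 11 --out tables/
Rscript -e 'vepvuln::vepvuln_cli()' paths --in survey.csv --boot 500 --seed 13 --out paths.json
Rscript -e 'vepvuln::vepvuln_cli()' run --n 4371 --seed 1 --out run/
```

(`inst/exec/vepvuln` is an equivalent installed launcher.) Configuration
files are JSON, mirroring the constructor arguments of `synthetic_config()`,
`income_model_spec()`, `construct_spec()` and `path_diagram()`.

## Documentation

See the methods vignette (`vignettes/methods.Rmd`) for the model, its
assumptions, what the synthetic generator does and does not emulate, and the
package's numerical conventions.
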