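# mmgrowth

Individual-level modelling of infant growth (birth to 36 months) with a
modified Michaelis–Menten curve.

Population growth charts describe cohorts; they cannot impute a missing
weight or height for one particular child. **mmgrowth** fits each child's
own longitudinal series with the three-parameter saturating curve

    P(t) = c1 + a1 * t / (b1 + t)

where `t` is age in days, `c1` is the value at age 0 (empirically the birth
weight in kg or birth length in cm), `a1` the asymptotic gain above birth
size, and `b1` the half-saturation age in days. The fitted curve
interpolates missing measurements, flags children whose near-linear growth
defeats a saturating model (the parameters diverge rather than converge —
a feature, reported as a status), and extrapolates early measurements to
predict size at 36 months.

The package is aimed at pediatric and epidemiological researchers working
with longitudinal anthropometry — birth cohorts, EMR extracts — who need
per-child interpolation, a missing-visit sensitivity analysis, or a simple
baseline growth model to compare richer models against.

## What is in the box

* `mm_growth()` / `fit_mm()` — Gauss–Newton nonlinear least squares with
  step-halving, divergence detection and the published starting triples;
  returns a classed object with `print`, `summary`, `coef`, `predict`,
  `residuals`, `fitted`, `plot` and `simulate` methods.
* `load_cohort()`, `clean_cohort()`, `flag_implausible()`,
  `visit_schedule()`, `assign_visits()` — long-format CSV I/O, the protocol
  cleaning rules (1,125-day cutoff, neonatal weight exclusion, ≥5
  observations) and the 12 well-baby visit windows.
* `imputation_experiment()`, `holdout_experiment()`,
  `prediction_experiment()` / `prediction_table()` — the three evaluation
  protocols, with LOCF / linear / LOESS / smoothing-spline baselines and a
  pluggable interface for external growth models.
* `cohort_config()` / `generate_cohort()` — a synthetic-cohort generator
  with known ground truth (calibrated parameter distributions, visit
  windows, measurement noise, linear growers).
* `inst/scripts/mmgrowth-cli.R` — a thin command-line front end
  (`simulate | fit | holdout | impute-study | predict | report`).

## Worked example

```r
library(mmgrowth)

baby <- data.frame(age_days  = c(1, 32, 61, 120, 190, 274, 365, 550, 730, 1095),
                   weight_kg = c(3.5, 4.9, 5.9, 7.3, 8.3, 9.2, 9.9, 11.1, 11.9, 13.1))
fit <- mm_growth(weight_kg ~ age_days, baby)
fit
#> Modified Michaelis-Menten growth fit (weight)
#> Status: converged after 9 iterations
#> Parameters:
#>     a1     b1     c1
#>  11.57 290.20   3.69
#> RMSE: 0.178 on 10 measurements
```

The child starts near `c1 = 3.69` kg, will gain about `a1 = 11.6` kg in
total (asymptote ≈ 15.3 kg), and reached half of that gain at `b1 = 290`
days. The RMSE of 0.18 kg is the typical size of a measurement's deviation
from the fitted curve. Missing values are interpolated by predicting at any
age:

```r
round(predict(fit, ages = c(90, 450, 1000)), 2)
#> [1]  6.43 10.72 12.65
```

On a synthetic 200-child cohort with known truth, holding out one random
non-birth point per child and letting each method predict it:

```r
g <- generate_cohort(cohort_config(n_subjects = 200, seed = 42))
h <- holdout_experiment(g$cohort, seed = 1234)
run_report(h$summaries)
#>     row     mean (sd)  median (IQR) 90% <         range   n failures
#>      mm 0.171 (0.138) 0.123 (0.181) 0.341 0.00184-0.632 200        0
#>    locf  1.19 (0.894)     0.985 (1)  2.29   0.0158-5.64 200        0
#>  linear   1.29 (1.02)   1.06 (1.07)   2.7  0.00117-6.73 200        0
#>   loess   0.41 (1.28) 0.228 (0.296) 0.656   0.0137-17.5 200        0
#>  spline 0.298 (0.309) 0.218 (0.282) 0.592  0.00117-2.53 200        0
```

The saturating curve's mean holdout error (0.17 kg) sits at the measurement
noise floor (sd 0.2 kg) and below every baseline.

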