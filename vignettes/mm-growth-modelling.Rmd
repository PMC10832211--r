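---
title: "Modelling infant growth with a modified Michaelis-Menten curve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling infant growth with a modified Michaelis-Menten curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmgrowth)
```

## The model

Healthy growth in the first three years of life is rapid at first and
decelerates smoothly, much like the velocity of an enzyme-catalysed reaction
as substrate saturates. **mmgrowth** models an individual child's weight
(kg) or height (cm) at age $t$ days as a saturating hyperbola with a
non-zero intercept,

$$P(t) \;=\; c_1 + a_1\,\frac{t}{b_1 + t},$$

with three parameters per child: $c_1$, the value at age 0, which
empirically approximates birth weight or birth length; $a_1$, the total
asymptotic gain above birth size ($P \to a_1 + c_1$ as $t \to \infty$); and
$b_1$, the half-saturation age — the age in days at which half of $a_1$ has
been attained. The model is deliberately simple (three parameters against
typically 9-12 measurements) so that it smooths noisy series without
overfitting, and its whole purpose is *individual-level interpolation*:
population reference charts cannot impute a missing measurement for one
particular child, a per-child fitted curve can.

The parameters are estimated by unconstrained nonlinear least squares. We
use plain Gauss-Newton with a step-halving line search (up to 10 halvings
per iteration; the step is accepted as soon as the sum of squared residuals
does not increase). Convergence is declared when the relative SSE
improvement of an accepted step falls below $10^{-10}$ or the largest
relative parameter change falls below $10^{-8}$; the iteration budget is 50.
These tolerances are our own choices; they drive the gradient condition
$\|J^\top r\|$ far below $10^{-6}\,\|r\|$ in practice, which the test suite
asserts, and the converged SSE agrees with an independent grid-plus-polish
brute-force minimiser to $10^{-6}$ relative on random instances.

### Failure is informative

The objective is not convex in $(a_1, b_1)$, and for a child whose growth is
essentially *linear* over the window the saturating curve has no finite
optimum: the fit pushes $a_1, b_1 \to \infty$ jointly with $a_1/b_1$
approaching the slope. We detect this as it happens: when $|a_1|$ or
$|b_1|$ exceeds `divergence_bound` ($10^7$ by default) or the SSE becomes
non-finite, the fit returns status `diverged_unbounded` with no parameters.
The normal equations are solved with an effectively zero pivot tolerance so
that the near-singular systems typical of this regime still produce steps —
aborting at the first ill-conditioned iteration would mask the divergence
signature as a generic numerical failure. Genuinely unsolvable systems, and
convergence to a non-physical optimum ($a_1 \le 0$ or $b_1 \le 0$, checked
after the fact; iteration itself is unconstrained), are reported as
`singular`. No standard errors are reported: the object of interest is the
fitted curve, not parameter inference.

Starting values matter in this landscape. The defaults,
$(a_1, b_1, c_1) = (5, 20, 2.5)$ for weight and $(60, 530, 50)$ for height,
are low relative to the population medians; starts near the medians give
similar estimates where both converge, but fail more often. When a series
lacks its birth record the low start can stall; `fit_mm(..., rescue = TRUE)`
retries once from the higher rescue start $(15, 500)$.

Goodness of fit is the root-mean-squared error with denominator $n$ — no
degrees-of-freedom correction, matching the plain mean-squared-error
convention used throughout the evaluation protocols. Duplicate ages are
allowed and all enter the SSE; ages are integer days since birth.

## Data rules

Cohorts are long-format tables (`subject_id, sex, measure, age_days, value`,
optionally `unit` with `lb` converted on load as 1 lb = 0.45359237 kg).
Cleaning follows the study protocol: values beyond 1,125 days are dropped;
weights between day 1 and day 19 are dropped, because post-natal weight
loss in that window would distort the curve — the birth record itself
(day 0 or 1) is exempt, and we accept either day-0 or day-1 records as the
birth visit, keeping the earliest on a tie; subjects retaining fewer than 5
measurements are excluded (an exclusion, not an error). An advisory
implausibility screen replaces manual two-reviewer adjudication, which is
not reproducible: it flags height decreases beyond 0.5 cm and robust
z-scores above 5 computed from the median/MAD of residuals about a running
median (falling back to IQR and then mean absolute deviation when the MAD
degenerates on exact-fit series). The screen only flags; removal is a
configuration choice, and it is off for synthetic data.

The 12 recommended well-baby visits are day windows (closed intervals):
day 0-1, then 20-44, 46-90, 95-148, 158-225, 250-298, 310-399, 410-490,
500-600, 640-800, 842-982 and 1024-1125. When several measurements fall in
one window the one closest to the window midpoint is chosen, ties to the
earlier age — the protocol does not say how to resolve duplicates, so we
fixed the most schedule-faithful deterministic rule.

## The three evaluation protocols

**Visit-dropping imputation.** Restricted to subjects with all scheduled
visits through visit 7 (first year) or 12 (three years), the model is fitted
to all subset visits (baseline), then refitted with every combination of up
to five visits removed. Each refit is scored by its RMSE over *all* subset
measurements, dropped visits included, so the score directly measures how
well the reduced data impute the missing visits; the baseline comparison
then isolates the information each visit carries. (The protocol source does
not state the evaluation set for the reduced fits; scoring on all visits is
the reading under which the study question — which visits can be missed? —
is answerable, and it makes the empty drop-set delta exactly zero by
construction.) Combinations leaving fewer than 3 points are reported as
degenerate rather than fitted.

**Single-point holdout.** One measurement other than the birth record is
removed from each subject uniformly at random; every interpolation method
fits the remaining points and predicts at the held-out age, scored by the
absolute error (the single-point RMSE). The holdout draw is seeded (default
1234, following the original analysis convention) and depends only on the
cohort and the seed, never on the method list, so methods always face
identical holdouts; bit-identical selections with other implementations are
not promised, only internal reproducibility. Built-in baselines: last
observation carried forward, the OLS line, LOESS (degree 2, span 0.75,
direct surface) and a GCV cubic smoothing spline, both falling back to the
line with a warning below 4 distinct ages. External growth models (SITAR,
FACE, multilevel splines, ...) plug in as functions `f(age, value, at)`;
they are not re-implemented here. Subjects whose saturating-curve refit
fails are dropped from *every* method's summary — a paired design keeps the
comparison honest, at the cost of summarising a slightly easier population.

**Last-value prediction.** Can measurements up to 12 or 24 months predict
size at 36 months? Eligible subjects need at least 5 points in year 1 and
at least 2 in each of years 2 and 3 (years are days 0-365, 366-730,
731-1125, closed; the protocol gives months only, so we fixed day bounds
once). The curve is fitted to the early window only and scored by the RMSE
of its predictions at the subject's *actual* later measurement ages — not a
fixed grid — with the full-data fit as baseline. `prediction_table()`
assembles the five standard (fit window, evaluation window) rows.

Per-subject RMSE vectors are summarised as mean, sd ($n-1$), median, IQR
($p_{75}-p_{25}$), the 90th percentile and the range, with quantiles by
linear interpolation between order statistics (R's default type 7) — fixed
here because the IQR convention changes the printed numbers.

## The synthetic cohort generator

Real patient data cannot ship with a package, so every protocol is exercised
on synthetic cohorts with known ground truth. The generator emulates a large
outpatient pediatric sample:

* **Parameter marginals.** $a_1$ and $b_1$ are log-normal — their empirical
  distributions are right-skewed — with medians matched to the reported
  per-sex population medians (boys' weight: 14.1 kg and 393 d; girls: 14.7
  and 499; heights 62.0/502 and 64.5/547 cm/d) and log-scales chosen so the
  lognormal IQR reproduces the reported IQRs (e.g. 5.77 kg and 327 d for
  boys' weight). $c_1$ is normal (weight: mean 3.35/3.24 kg, sd 0.5;
  height: 51.0/50.5 cm, sd 2.5), consistent with its empirical normality
  and its role as birth size. Only medians, IQRs and ranges of the real
  parameters are published; the generative families are our modelling
  choice, so the defaults are calibration targets, not estimates of the
  true joint distribution.
* **Dependence.** A Gaussian copula couples $c_1$ with $a_1$ and with $b_1$
  at Spearman rank correlation 0.30 (the reported weak association of birth
  size with the shape parameters); rank correlations pass through the
  monotone marginal transforms, so the latent Pearson correlation is
  $2\sin(\pi \rho / 6)$. The $a_1$-$b_1$ latent correlation defaults to 0.5
  — unreported, chosen once on the rationale that larger total gains tend
  to be reached later; it is a config knob, and no result in this package
  depends on it sensitively.
* **Sampling frame.** Visit 1 is the birth record at day 1; visits 2-12 get
  integer ages uniform in their windows and are dropped independently with
  probability 0.2, which reproduces the typical 9-of-12 observed-visit
  count of EMR cohorts. The birth record has its own missingness
  probability, 0 by default: birth size comes from the delivery record and
  is present for essentially every child followed from birth, unlike a
  well-baby visit that can be skipped. Measurement noise is homoscedastic
  Gaussian, sd 0.2 kg (weight) or 1.0 cm (height) — the scale implied by
  the reported median fit RMSEs — floored at 0.1 units; an optional switch
  makes the sd grow linearly to twice its value at 36 months, emulating the
  slight increase of residuals with age seen in real data.
* **Linear growers.** A fraction (default 1%) of children grow linearly —
  the regime that defeats the saturating model. Each follows the line from
  $(0, c_1)$ that reaches, at day 1095, the size its own sampled curve
  would have reached, so linear growers sit inside the cohort's size
  distribution. Sexes and linear-grower flags are stratified
  deterministically along the subject index (exact counts, and appending
  subjects never changes earlier subjects); all other draws flow from one
  master seed through per-subject derived streams.

What passing tests on this generator do **not** show: robustness to real
EMR artefacts (transcription errors, unit mix-ups, shared family records),
to informative missingness (sick children visit more often), or to growth
patterns outside the healthy-term-infant regime the curve was built for —
premature infants, catch-up growth, endocrine disease. The generator's
noise is also exchangeable within a child, whereas real measurement error
has within-visit structure (clothed vs unclothed weighings).

## Problem sizes and numerical choices

The shipped tests run the protocols at deliberately modest sizes — oracle
equivalence on 20 random 5-12-point instances against a 70x70
grid-plus-polish brute force; parameter recovery on 500 subjects per sex;
holdout at 500 subjects; imputation at 200 subjects with drops up to size
3 on the first-year subset — sizes at which the Monte-Carlo properties
asserted (convergence above 99%, median $c_1$ error under 5%, median fit
RMSE within $[0.7\sigma, 1.1\sigma]$, birth-visit primacy in the imputation
deltas, the curve matching or beating every baseline on held-out points)
are stable across seeds. The full protocol (drops up to 5 visits on the
12-visit subset, i.e. 2,509 combinations) runs with the same code path via
`imputation_experiment(co, subset = 12, max_drop = 5)`.

Degenerate inputs are handled as values, not crashes, wherever the protocol
treats them as data: too few points, all-linear cohorts and failed fits
flow into status columns and failure counts; true errors (negative weights,
missing columns, unknown methods) stop immediately.

## Known limitations

The fitted curve is strictly monotone and saturating: it cannot represent
growth faltering followed by catch-up, and extrapolation beyond 36 months
is outside its design (growth after infancy, let alone puberty, does not
follow this curve). The per-subject eligibility and failure rates of the
original clinical cohorts cannot be reproduced exactly without their data;
the synthetic defaults reproduce the qualitative findings and the scale of
the quantitative ones, which is what the acceptance checks assert.
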