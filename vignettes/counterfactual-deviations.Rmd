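---
title: "Counterfactual deviation analysis of monthly care-utilization panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual deviation analysis of monthly care-utilization panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CareDelta)
```

## The problem

When access to healthcare is disrupted for an extended period — a pandemic
being the motivating case — utilization shifts differently across hundreds
of diagnoses at once. Some conditions lose most of their patient volume and
never fully regain it; others, typically the more severe or emergent ones,
are prioritized and rebound quickly. Quantifying these shifts requires, for
every diagnosis entity (a clinically coherent grouping of diagnosis codes
tracked as one monthly count series), an estimate of the patient volume that
*would have been observed without the disruption*, and a calibrated way to
measure how far the observed counts fall from it.

CareDelta implements that workflow end to end:

1. **Counterfactual modelling.** Per entity, candidate seasonal-trend
   Poisson log-linear models are scored by leave-one-year-out blocked
   cross-validation on pre-disruption data; the winner is refit, assessed
   for overdispersion, and used to simulate a Monte-Carlo counterfactual
   count distribution for the disruption window, with 95% prediction
   intervals.
2. **Deviation inference.** For each month, calendar quarter, and named
   summary period, the relative deviation
   $\delta = (\mathrm{observed} - \mathrm{expected}) / \mathrm{expected}$
   is estimated with a percentile confidence interval and a two-sided
   add-one empirical p-value from the counterfactual draws, followed by
   Benjamini–Hochberg FDR adjustment across entities.
3. **Trajectory characterization.** Recovery classification (none /
   partial / sustained), hierarchical clustering of quarterly deviation
   trajectories (Euclidean distance, complete linkage), heatmap intensity
   scores, and severity-association tests (OLS slope, Wilcoxon rank-sum,
   Kruskal–Wallis).
4. **Synthetic registry panels.** Because the registries such analyses run
   on are typically proprietary, a first-class generator produces
   registry-like panels with known ground truth — planted seasonality,
   trend, dispersion, shock trajectories, cluster structure and
   severity-dependent shock depths — so every stage is testable.

## The counterfactual model

For entity $i$ with monthly count $y_{it}$, the candidate models are
Poisson GLMs with log link,

$$\log \mu_{it} = \beta_0 + \beta_{\mathrm{trend}}\,\mathrm{year}(t) + s(t),$$

where $\mathrm{year}(t)$ is the 0-based calendar-year index from the first
training month and $s(t)$ is one of five seasonality blocks: none; harmonic
pairs $\sin(2\pi t/P), \cos(2\pi t/P)$ for periods $P \in \{12\}$,
$\{12,6\}$, or $\{12,6,3\}$ months; or eleven month-of-year indicators with
January as reference. Crossing the five blocks with presence/absence of the
trend yields ten candidates with 1–13 parameters
(`enumerateCandidates()`).

**Blocked cross-validation.** Folds are whole calendar years of the
training window, respecting temporal structure. Each candidate is fit on
all other years and scored by the mean squared error between held-out
counts and predicted means; the lowest average MSE wins, with ties broken
by fewest parameters, then lowest candidate id. Candidates that fail to
converge (or are rank-deficient) in any fold are dropped; if all fail, the
intercept-plus-trend model is the fallback. The held-out predictions of the
winner also yield the out-of-sample root-mean-squared percentage error
(RMSPE), used for quality filtering.

**Dispersion routing.** The Pearson dispersion of the final training fit,
$\hat\varphi = \sum_t (y_t-\hat\mu_t)^2/\hat\mu_t \,/\, (n-p)$, decides the
simulation family. At $\hat\varphi \le 1.2$ counts are treated as Poisson;
beyond that, the excess squared residual $(y-\hat\mu)^2 - \hat\mu$ is
regressed through the origin on $\hat\mu$ (overdispersed Poisson, variance
$\varphi\mu$) and on $\hat\mu^2$ (negative binomial, variance
$\mu + \mu^2/\theta$), and the form with the smaller residual sum of
squares is used. The 1.2 trigger sits roughly one standard error of
$\hat\varphi$ above 1 for a three-year monthly series, so mild sampling
fluctuation keeps the simpler family. Guards keep $\varphi > 1$ and
$\theta$ positive; a non-positive negative-binomial slope routes to the
overdispersed-Poisson form.

**Monte-Carlo counterfactuals.** Draws are conditionally independent
counts: Poisson($\hat\mu$); for the overdispersed-Poisson family a
moment-matched negative binomial with size $\hat\mu/(\varphi-1)$, which is
integer-valued with variance exactly $\varphi\hat\mu$; or negative binomial
with size $\theta$. Prediction intervals use inverted-ECDF order statistics
(lower = $\lceil \alpha/2 \cdot S\rceil$-th smallest draw), which are
well-defined on integer draws and never interpolate to non-counts. The
registry-scale default is 100,000 draws; the package default (10,000) gives
confidence-limit Monte-Carlo error scaling as $1/\sqrt{S}$ and is
appropriate at desk scale — the full-scale runs in this package's checks
use 1,000–10,000 draws per entity-month.

**Estimation uncertainty.** By default draws are conditional on the fitted
mean: they represent outcome noise only, matching a reading of the
framework in which simulations come from the conditional count
distribution. When the prediction window extends well beyond the training
support (two extrapolated years here), coefficient estimation error —
especially of a secular trend — becomes a non-negligible share of
predictive uncertainty, and conditional intervals under-cover. The
`resampleCoefficients` switch therefore optionally resamples the
coefficient vector per draw from its asymptotic normal distribution
(inverse Fisher information of the final fit, inflated by the dispersion
estimate for non-Poisson families). It is off by default; the calibration
study below turns it on, because total predictive coverage is the property
being calibrated. Model-*selection* uncertainty (e.g., cross-validation
dropping a small true trend that then matters two years out) is propagated
by neither mode and remains a known limitation.

## Deviation inference

The point deviation for a month is
$\delta = (y - \hat\mu)/\hat\mu$ with $\hat\mu$ the model mean (not the
draw average, so the point estimate is deterministic and independent of
the number of draws). Per-draw deviations $(y - y_s)/y_s$ — with draws
floored at 0.5 and flagged if more than 0.1% of them are zero, a situation
the single-digit inclusion rule makes rare — give the 95% percentile
confidence interval. The two-sided empirical p-value uses the add-one rule
$p = \min\!\big(1,\, 2\min\big(\tfrac{1+\#\{y_s \le y\}}{S+1},
\tfrac{1+\#\{y_s \ge y\}}{S+1}\big)\big)$, which cannot reach zero and is
standard Monte-Carlo practice.

Summary timeframes (calendar quarters Q3 2020–Q4 2021 and named periods:
hiatus March–May 2020, post-hiatus June 2020–December 2021, and the full
2020–2021 window) average the monthly deviations; the per-draw joint
distribution is the column-wise mean $\bar d_s$ of the per-month per-draw
deviations, the CI its percentile interval, and the p-value asks whether
that distribution straddles zero. A one-month period thus reproduces the
monthly $\delta$ and CI exactly; its p-value is formulated on $\bar d_s$
rather than count tails, which coincides in distribution for symmetric
draws. June 2020 belongs to the post-hiatus average but to no clustered
quarter.

FDR adjustment is applied in three separate families — all entities ×
pandemic months, all entities × quarters, and all entities within each
named period — reflecting that monthly and quarterly deviations are
reported as complete testing families.

## Recovery, clustering, severity

A month is *bad* when $\delta < 0$ and adjusted $p \le 0.05$. Recovery is
the first run of at least three consecutive non-bad months; its start
index (January 2020 = 1) dates the recovery. Recovery is *sustained* when
no bad month occurs from that start onward, *partial* otherwise; the
start-anchored reading is used because the recovery date refers to the
run's first month. A trailing non-bad run shorter than three months is not
a recovery. Note the status is deliberately not monotone in the bad flags:
clearing a flag can open an earlier qualifying run whose later bad months
make the classification partial — the classifier follows the rule, which
is checked against a brute-force run scanner over all $2^{12}$ patterns.

Quarterly point-estimate deviations (entities × 6 quarters) are clustered
with Euclidean distance and complete linkage; the number of clusters `k`
is a configuration parameter — no value is canonical, so the dendrogram
and leaf order are always exported for k-free use. Heatmap cells are
scored as $\mathrm{sign}(\delta)\,|\delta| \cdot
(-\log_{10} \max(p_{\mathrm{adj}}, 10^{-10}))$; base 10 is conventional
for p-values and the floor keeps intensities finite.

Severity association uses ordinary least squares of deviations on ordinal
severity ranks (1 = least severe … 5), Wilcoxon rank-sum between
vision-threatening and non-vision-threatening groups (exact enumeration
when the pooled size is at most 12 without ties, tie-corrected normal
approximation otherwise), and Kruskal–Wallis across severity strata (tie
corrected; fully tied data is reported as $H = 0$, $p = 1$ since the
statistic is undefined after correction).

## The synthetic generator

Counts are drawn from
$y_{it} \sim \mathrm{Poisson}$ or $\mathrm{NB}(\theta)$ with mean
$\exp(\beta_0 + \beta_{\mathrm{trend}}\,\mathrm{year} +
a\sin(2\pi t/12 + \phi)) \cdot m(t)$, where $m(t)$ is a piecewise shock
multiplier: 1 before onset, linear descent to $1-A$ at the nadir, then
exponential approach at rate $r$ per month toward the plateau $1-B$. The
source analyses describe the empirical shape (deep spring-2020 dip, nadir
in April 2020, partial plateau below baseline afterwards) but no
generative model; this minimal parameterization reproduces that shape and
nothing more. Defaults: onset March 2020, nadir April 2020, $r = 4$ per
month, so the plateau is reached within about two months of the nadir —
matching a rebound essentially complete by June 2020. The default mean
floor of 15 patients/month keeps generated panels above the single-digit
inclusion rule by construction. Severity-mapped shocks use
$A = 0.9 - 0.1\,\mathrm{rank}$ and $B = 0.25 - 0.04\,\mathrm{rank}$ —
monotone, so more severe conditions are planted with shallower drops, and
spanning deviation magnitudes comparable to those reported for real
registries. Entity parameters ($\beta_0$ uniform on $[5, 6.5]$ log scale,
i.e. baseline means of roughly 150–660 patients/month; trend within
±4%/year; annual log-amplitude 0.1–0.3) are drawn from per-entity
substreams keyed by a stable hash of (master seed, entity id), so panels
are byte-identical across runs and independent of entity ordering.

What the generator does *not* emulate: patient-level visit processes,
coding-practice drift, reporting gaps or practice churn (panels are
generated already clean, standing in for the upstream practice-continuity
filter real registries require), and non-stationarities outside the
candidate model class. Passing checks on these panels therefore establish
the statistical machinery's correctness and calibration under a
well-specified data-generating process, not robustness to the messiness of
real registry extraction.

## Study conditions used by the package's checks

- **Shock recovery** (100 entities, Poisson, baseline means ≥ 200, annual
  seasonality, $A = 0.67$, $B = 0.13$, 5,000 draws): the across-entity
  mean April 2020 deviation and mean post-hiatus deviation recover the
  planted −0.67 and −0.13.
- **Calibration** (200 no-shock entities, stationary seasonal baselines,
  2,000 draws, `resampleCoefficients = TRUE`): 95% PI coverage over
  200 × 24 entity-months, BH-significant fraction at $q = 0.05$, and
  p-value decile uniformity. The null panel is stationary because the
  calibration isolates the uncertainty the simulator represents; with
  planted secular trends, model-selection error (a trend dropped by CV)
  degrades coverage, which is the limitation discussed above rather than
  a property of the interval machinery.
- **Selection and routing** (36-month series): planted annual seasonality
  of log-amplitude 0.35 with trend; Poisson and negative-binomial
  ($\theta = 5$) series at mean 100. Note the Poisson-routing probability
  under the $\hat\varphi > 1.2$ trigger is only about 0.81 by construction
  ($P(\chi^2_{n-p} \le 1.2 (n-p))$ at $n - p = 35$), so this check sits
  close to its own expected value.
- **Cluster recovery** (40 entities in two planted shock trajectories,
  plateau gap 0.4): adjusted Rand index against planted labels.
- **Scale** (261 entities × 60 months, 10,000 draws): a full pipeline run
  on one CPU, with a byte-identical deterministic re-run.

These sizes were chosen as desk-scale analogues of a registry analysis:
large enough for across-entity averages and calibration rates to be
stable, small enough to run interactively.

## A worked example

```{r example, eval = FALSE}
library(CareDelta)

## a synthetic registry panel: 20 entities, Jan 2017 - Dec 2021,
## pandemic-style shock (nadir multiplier 0.33 in April 2020)
sim <- simulatePanel(simConfig(nEntities = 20), seed = 1)
sim$panel

run <- runPipeline(sim$panel, nSims = 5000, seed = 1, k = 2)

## headline summaries
run$report$summaries$nadir_month      # mean/SD April 2020 deviation
run$report$summaries$periods$post_hiatus
table(run$recovery$status)

## per-entity results
head(run$deviations)
run$models
```

## Numerical choices and degenerate inputs

- IRLS convergence at relative deviance change $10^{-8}$, at most 100
  iterations; non-convergence and rank deficiency drop a candidate in CV
  rather than aborting the entity.
- Order-statistic (inverted-ECDF) quantiles everywhere intervals are
  formed from draws; no interpolation, bounds are attainable counts.
- Exact ties in CV scores are broken by parameter count, then candidate
  id; floating-point near-ties are not collapsed.
- Degenerate draw distributions give zero-width intervals and $p = 1$;
  fully tied rank-test inputs give $p = 1$; zero draws are floored at 0.5
  before the deviation transform and flagged when above 0.1% of draws.
- p-values are validated to lie in $(0, 1]$ before BH adjustment.

## Limitations

Beyond the generator's idealizations listed above: model-selection
uncertainty is not propagated into intervals; deviations are relative, so
entities near the count floor have noisier $\delta$; the severity mapping
is a planted stand-in, not an external clinical severity measure; and the
framework estimates utilization shifts, not their clinical consequences.
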