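# CareDelta

Counterfactual deviation analysis of monthly healthcare-utilization count
panels.

## What it does, and for whom

During a prolonged disruption to healthcare access — the COVID-19 pandemic
being the motivating case — patient volumes shift differently across
hundreds of diagnoses at once. Health-services researchers studying such
shifts need, for every *diagnosis entity* (a clinically coherent group of
diagnosis codes tracked as one monthly patient-count series), an estimate
of the utilization expected *in the absence of the disruption*, and
calibrated statistics for how far observed volumes deviate from it.

CareDelta implements that common analytical framework end to end:

1. **Counterfactual forecasting.** Per entity, ten candidate Poisson
   log-linear models — crossing five seasonality blocks (none; harmonics
   with 12-, 12+6-, or 12+6+3-month periods; monthly fixed effects) with a
   linear year trend — are scored by leave-one-year-out blocked
   cross-validation on pre-disruption data (lowest mean holdout MSE wins,
   parsimony breaks ties). The winner is refit, assessed for
   overdispersion via the Pearson statistic and the mean-variance
   relationship of its residuals, and routed to Poisson,
   overdispersed-Poisson (variance φμ) or negative-binomial (variance
   μ + μ²/θ) Monte-Carlo simulation of the counterfactual count
   distribution, with order-statistic 95% prediction intervals.
2. **Deviation inference.** The primary outcome per month, quarter and
   summary period is

   δ = (observed − expected) / expected,

   with percentile confidence intervals and two-sided add-one empirical
   p-values referenced to the counterfactual draws, and
   Benjamini–Hochberg FDR adjustment (threshold 0.05) across entities.
3. **Pattern analysis.** Recovery classification (≥ 3 consecutive months
   without a significant negative deviation; sustained vs partial),
   hierarchical clustering of quarterly deviation trajectories (Euclidean
   distance, complete linkage), heatmap intensities
   (|δ| · −log₁₀ adjusted p, signed), and severity-association tests
   (OLS slope on severity ranks, Wilcoxon rank-sum, Kruskal–Wallis).
4. **Synthetic registry panels.** Registries backing such analyses are
   proprietary, so a first-class generator produces panels with known
   ground truth — seasonality, trend, dispersion, a configurable
   dip/rebound/plateau shock, planted clusters and severity gradients —
   making every stage verifiable.

Entities whose counts fall to single digits in any month, or whose
selected model has out-of-sample RMSPE ≥ 12.5%, are excluded, mirroring
standard inclusion rules for this kind of analysis.

## A worked example

```r
library(CareDelta)

sim <- simulatePanel(simConfig(nEntities = 20), seed = 1)
sim$panel
#> MonthlyPanel: 20 entities x 60 months [ 2017-01 .. 2021-12 ]
#> categories: retina, cornea, glaucoma, cataract, neuro

run <- runPipeline(sim$panel, nSims = 5000, seed = 1, k = 2)

str(run$report$summaries$nadir_month)     # April 2020 deviations
#> List of 2
#>  $ mean: num -0.672
#>  $ sd  : num 0.0225
str(run$report$summaries$periods$post_hiatus)
#> List of 2
#>  $ mean: num -0.138
#>  $ sd  : num 0.0298
table(run$recovery$status)
#>    none partial
#>      11       9
```

The generator's default shock multiplies expected volume by 0.33 in April
2020 and plateaus at 0.87 from mid-2020; the pipeline recovers those
planted truths as a mean April deviation of −0.672 (SD 0.022) and a mean
post-hiatus (June 2020–December 2021) deviation of −0.138. Per-entity
detail:

```r
head(run$deviations, 4)
#>   entity_id timeframe_type timeframe     delta ci_lower ci_upper p_value p_adjusted
#> 1      E001          month   2020-01  0.000238  -0.0713   0.0832  1.0000    1.00000
#> 2      E001          month   2020-02 -0.014696  -0.0873   0.0707  0.7479    0.77364
#> 3      E001          month   2020-03 -0.350210  -0.3981  -0.2951  0.0004    0.00145
#> 4      E001          month   2020-04 -0.652748  -0.6781  -0.6230  0.0004    0.00145

head(run$models, 4)
#>   entity_id        seasonal trend  family  rmspe
#> 1      E001     harmonics12  TRUE poisson 0.0414
#> 2      E002     harmonics12 FALSE poisson 0.0523
#> 3      E003     harmonics12  TRUE poisson 0.0832
#> 4      E004 harmonics12_6_3 FALSE poisson 0.0427
```

E001's utilization is indistinguishable from its counterfactual in
January–February 2020 (p ≈ 1), drops 35% in March and 65% in April (both
significant after FDR adjustment), and its selected counterfactual model
is an annual-harmonic Poisson GLM with trend, out-of-sample RMSPE 4.1%.

`runPipeline(..., outDir = "out")` additionally writes `deviations.csv`,
`prediction_intervals.csv`, `recovery.csv`, `clusters.csv` (plus a Newick
dendrogram), `heatmap_matrix.csv`, `severity_tests.json` and
`report.json`.

See the vignette (`vignettes/counterfactual-deviations.Rmd`) for the
model, its assumptions, tuning parameters and limitations.

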