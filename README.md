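# markresight

Mark-resight abundance estimation for nesting sea turtle rookeries.

At very large rookeries — the canonical case is the green turtle
(*Chelonia mydas*) rookery at Raine Island, northern Great Barrier Reef —
nester abundance is monitored by painting a white stripe on the carapace of
every suitable nesting female on a single night (up to ~2000 turtles), then
counting painted and unpainted turtles in the adjacent inter-nesting waters
over the following days. Counts are made by a surface observer on a small
boat (SO), by hull-mounted underwater video (UWV), or by a UAV flown along
the reef edge (UAV). `markresight` implements the full analysis chain for
such programmes:

- **Lincoln-Petersen estimation** from repeated resight surveys. With `M`
  marked turtles, `C` turtles sighted in a survey and `R` of them marked,
  the abundance estimate is `N̂ = M·C/R` with large-sample standard error
  `√(M²C(C−R)/R³)`; period-level estimates average the repeated surveys. A
  Chapman variant `(M+1)(C+1)/(R+1) − 1` is available for sparse counts.
- **Cumulative-sampling precision**: `N̂` from cumulative average counts as
  surveys accumulate (up to six over three days), with leave-one-out
  jackknife 95% intervals — quantifying how many repeat surveys a
  monitoring design actually needs.
- **A Bayesian binomial mixed model of marked-turtle detectability**
  (`R_ijk ~ Binomial(N_ijk, P_ijk)`,
  `logit(P_ijk) = α + β·method + b_i + b_ij + b_ijk + ε_ijk`) with nested
  random intercepts for survey period, day and diel slot and an
  observation-level dispersion term, fitted by a built-in
  Metropolis-within-Gibbs sampler with vague priors. Method contrasts in
  the proportion of detections that are marked are the signature of
  marked-detection bias — a surface observer spots a white-striped turtle
  more easily than an unmarked one, which violates the Lincoln-Petersen
  equal-detectability assumption and deflates `N̂`.
- **Conversion factors** between methods (per-period quotients of
  period-mean estimates) for splicing modern UAV/video estimates onto the
  historical surface-observer series, with an exact-permutation Spearman
  test of their trend with abundance, and likelihood-ratio comparisons of
  per-method totals and densities.
- **Survey geometry**: field-of-view, swathe-width, area and density
  calculators for the three platforms, and the Welch t analysis of the
  submerged-model depth-detectability experiment.
- **A synthetic-data generator** with the statistical structure the
  estimators assume (closed population, method-specific detection,
  odds-ratio marked-detection bias, nested logit-scale random effects,
  optional departure), so every stage is testable by parameter recovery.

## Worked example

Simulate a six-period programme under the default study conditions (marked
cohorts of 482–2000, three survey days, AM/PM slots, three methods, a 1.6
odds marked-detection bias for the surface observer only), then estimate:

```r
library(markresight)

d <- simulate_surveys(sim_config(seed = 42))
est <- lp_period_estimates(d)
est
#> # A tibble: 18 × 7
#>   period_id method n_surveys mean_total   n_hat    se source
#>   <chr>     <chr>      <int>      <dbl>   <dbl> <dbl> <chr>
#> 1 Dec 2013  SO             6      3786.  65932. 1994. period_mean
#> 2 Dec 2013  UWV            6      5611. 104523. 5015. period_mean
#> 3 Dec 2013  UAV            6      7430  105265. 2088. period_mean
#> 4 Dec 2014  SO             6      1243.  12852.  250. period_mean
#> # ...

glance(conversion_factor(est, "SO", "UAV"))
#> # A tibble: 1 × 5
#>   from  to    mean_cf  sd_cf n_periods
#>   <chr> <chr>   <dbl>  <dbl>     <int>
#> 1 SO    UAV      1.46 0.0931         6
```

The SO→UAV conversion factor of ~1.5 is the estimator-level consequence of
the simulated 1.6 detection-odds bias: the surface observer over-detects
marked turtles, inflating `R`, deflating `N̂`, so the unbiased UAV estimate
sits ~1.5× higher. Cumulative pooling shows precision stabilising after
about three surveys:

```r
cumulative_estimates(d, "Dec 2016", "UAV")
#> # A tibble: 6 × 6
#>   period_id method     k  n_hat ci_low ci_high
#> 1 Dec 2016  UAV        1 18216. 15019.  21414.
#> 2 Dec 2016  UAV        2 18507. 17885.  19129.
#> 3 Dec 2016  UAV        3 18608. 18139.  19078.
#> 4 Dec 2016  UAV        4 18851. 18222.  19480.
#> 5 Dec 2016  UAV        5 19147. 18329.  19966.
#> 6 Dec 2016  UAV        6 19488  18470.  20506.
```

The detectability model and its summaries:

```r
fit <- fit_detection_model(d, seed = 1)
tidy(fit)                  # posterior means, sds, 95% intervals
variance_partition(fit)    # share of variance per nesting level, with HPDs
marked_proportion(fit)     # per-method marked fraction of detections
autoplot(fit)              # posterior densities per method
```

The package also ships the published period-level survey summary for the
Raine Island programme (2013–2017), usable directly:

```r
pub <- raine_estimates()
glance(conversion_factor(pub, "SO", "UAV"))
#> 1 SO    UAV      1.72 0.184         2
compare_totals(pub)$by_method
#>   method n_periods mean_total mean_density
#> 1 SO             6      1228.        4094.
#> 2 UAV            2      3041.        5199.
#> 3 UWV            6      1496.        3739.
```

Geometry: a 20 mm-equivalent lens at 50 m altitude sweeps a
`swathe_width(50, horizontal_fov_from_focal(20))` = 90 m swathe; over a
6.5 km reef track that is `survey_area(90, 6.5)` = 0.585 km².

## Package layout

- `R/data-io.R` — dataset container, CSV readers/writers, validation
- `R/simulate.R` — synthetic survey and detectability-trial generators
- `R/lp.R` — Lincoln-Petersen, Chapman, period and cumulative estimates
- `R/glmm.R` — Bayesian detectability GLMM and posterior summaries
- `R/compare.R` — conversion factors, trend test, totals comparison
- `R/geometry.R` — field-of-view/swathe/area/density, Welch depth test
- `R/report.R` — one-shot pipeline report
- `vignettes/mark-resight-methods.Rmd` — the methods vignette
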