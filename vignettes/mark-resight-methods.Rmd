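---
title: "Methods: mark-resight abundance estimation at a turtle rookery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mark-resight abundance estimation at a turtle rookery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markresight)
```

## The estimation problem

A rookery programme paints a white stripe on every suitable nesting female
on one night — the marked cohort `M`, capped by logistics at about 2000 —
and then surveys the adjacent inter-nesting waters twice daily (morning
and afternoon) for the next three days. Each survey counts `C` turtles, of
which `R` carry the mark. Under the closed-population, equal-detectability
assumptions, the Lincoln-Petersen estimator `N̂ = M·C/R` recovers the
number of females using the habitat.

Both assumptions are worth worrying about. Closure holds only while the
inter-nesting females stay near the reef; the simulator exposes a per-day
`departure_prob` to probe the consequences of emigration. Equal
detectability fails in a specific, directional way: a white-striped turtle
is easier for a surface observer to pick out than an unmarked one, so `R`
is inflated relative to `C`, and `N̂` is biased low. Video-based methods
(hull camera, UAV) permit frame-by-frame review and are much less
susceptible. Quantifying that difference — and converting between methods'
scales — is the core of the package.

## The detectability model

The proportion of sighted turtles that are marked is modelled per survey
as

$$R_{ijk} \sim \mathrm{Binomial}(N_{ijk}, P_{ijk}), \qquad
\mathrm{logit}(P_{ijk}) = \alpha + \beta_{method} + b_i + b_{ij} + b_{ijk}
+ \varepsilon_{ijk},$$

with Gaussian nested random intercepts for survey period ($b_i$), day
within period ($b_{ij}$) and diel slot within day ($b_{ijk}$), and an
observation-level intercept $\varepsilon_{ijk}$. A binomial model has no
free residual variance, so the residual term is implemented as an
observation-level random intercept carrying extra-binomial dispersion —
the standard reading of a residual in this model class. The method fixed
effect uses the surface observer as reference level, so each $\beta$ is a
contrast against the historical method, which is how the monitoring
question is naturally posed. If marked and unmarked turtles were equally
detectable, $P$ would equal the marked fraction of the population for
every method and all $\beta$ would be zero.

"Vague priors" are made concrete as Gaussian(0, 10²) on $\alpha$ and
$\beta$ (essentially flat over any plausible logit) and half-Cauchy(5) on
each random-effect standard deviation — the modern weakly-informative
default for variance components, heavy-tailed enough not to fight the
data. The half-Cauchy is represented exactly as an inverse-gamma scale
mixture so that variance updates stay conjugate.

### Sampler

The posterior is sampled by a purpose-built Metropolis-within-Gibbs
scheme:

- random-walk Metropolis on $\alpha$ and each $\beta$;
- vectorised random-walk Metropolis on each level of latent intercepts
  (given the other levels, groups are conditionally independent, so a
  whole level updates in one sweep with per-group accept/reject);
- conjugate Gibbs draws for each variance through the inverse-gamma
  mixture;
- *translation moves* that shift mass along the likelihood-invariant
  directions ($\alpha$ versus the period intercepts, each parent level
  versus its children) — without these the intercept and the period
  effects are additively confounded and mix very slowly;
- an *interweaved scale move* per level: a random walk on
  $\log\sigma$ holding the standardised intercepts $u/\sigma$ fixed.
  This is the ancillarity–sufficiency interweaving remedy for the
  centred parameterisation's stickiness when a variance component is near
  zero (the observation-level component typically is).

Step sizes adapt only during burn-in, targeting ~37% acceptance. All
draws derive from the user seed; chain $c$ uses `seed + c − 1`, so fits
are exactly reproducible. Convergence is monitored with a split-chain
Gelman–Rubin statistic; on study-scale synthetic fits (6 periods × 6
surveys × 3 methods, 5000 iterations) it sits below 1.1 for every
parameter.

Correctness is checked three ways in the test suite: a prior-only run
(likelihood switched off) recovers the prior moments; with all variance
components pinned at zero the posterior means match a maximum-likelihood
logistic regression to within 0.05 on the logit scale; and across 20
seeded study-scale simulations the 95% credible intervals cover the
generating $\alpha$, $\beta$ and $\sigma_{period}$ in at least 18 fits.

### Reported summaries

`marked_proportion()` reports the inverse logit of the fixed linear
predictor — the conditional scale, random effects at zero. Whether
published per-method percentages marginalise over random effects is
rarely stated; the conditional scale is the default here because it is
what the fixed effects literally parameterise, and `marginal = TRUE`
averages over the fitted Gaussian random-effect distribution by
quadrature when the population-averaged number is wanted.
`variance_partition()` divides each draw's $\sigma^2_c$ by the sum over
the three grouping levels (period, day, diel); the observation-level
dispersion is reported alongside but not in the denominator, since the
partition question is about the survey design's nesting levels. HPD
intervals are computed as the shortest interval containing the stated
mass of the sorted draws. Degenerate draws with all three variances zero
are assigned uniform shares, with a warning.

## Lincoln-Petersen conventions

Per-survey variance uses the classical large-sample form
$M^2C(C-R)/R^3$; period-level tables report the mean of per-survey
estimates with the standard error of that mean (`sd/√n`), falling back to
the analytic form for a single survey. Published tables of this design
report period means "with standard error", and the SEM convention
reproduces that structure; it is isolated in `lp_se()`/`period_estimate()`
so either convention is one function away. Surveys with `R = 0` are
excluded from per-survey estimation with a warning rather than
Chapman-corrected — counts at a large rookery are in the hundreds to
thousands, so a zero is a data problem, not a small-sample fluctuation —
but `lp_chapman()` is available behind a flag for genuinely sparse
designs.

Cumulative estimates pool counts before the quotient:
$\hat N_k = M\,\bar C_{1..k}/\bar R_{1..k}$ over surveys ordered by (day,
AM before PM), the sampling chronology. Pooling counts (rather than
averaging per-survey quotients) is the natural reading of a "cumulative
average of marked and unmarked recaptures" and is more stable when a
single survey has few marked resights. Intervals for $k \ge 2$ are
normal-theory, symmetric, using the leave-one-out jackknife variance;
published figures of this kind do not specify their interval construction,
and the jackknife-normal form needs no distributional model of the counts.
At $k = 1$ the analytic standard error is used.

One caution established while validating the jackknife: with only two
surveys the jackknife width is proportional to the absolute difference of
two estimates, which is a noisy half-normal quantity, so on any single
period the $k = 2$ interval can by chance be narrower than the $k = 6$
interval (this happens ~40% of the time in simulation). The reliable
statement — the one the tests make — is about mean widths: averaged over
periods, width declines monotonically with pooling and changes by less
than 25% from $k = 3$ to $k = 6$, i.e. three surveys already buy most of
the precision.

## Conversion factors and comparisons

The conversion factor from method A to method B is the per-period
quotient of period-mean estimates $\hat N_B/\hat N_A$, averaged
arithmetically over the periods where both methods ran, with the sample
standard deviation across periods. The quotient orientation follows the
published values (factors above 1 for SO→UAV, i.e. target over source);
prose descriptions of such factors sometimes invert the ratio, so the
direction is documented on the object (`from`, `to`) rather than left
implicit. Aggregation is deliberately at the period level — quotients of
period means, then averaged — which matches the published SD for the
SO→UAV factor exactly; per-survey pairing would weight periods by survey
count instead.

The trend of the factor with abundance is tested by Spearman rank
correlation with the two-sided p-value obtained by complete enumeration
of all $n!$ permutations for $n \le 8$ (720 orderings at the typical
$n = 6$; printed p-values at such sample sizes are exact, not
asymptotic), with average ranks on ties; larger samples use the t
approximation. Constant inputs make $\rho$ undefined and error.
Per-method totals and densities are compared by a likelihood-ratio
deviance $D = 2(\ell_{full} - \ell_{null})$ for a Gaussian model on
natural-log period totals against $\chi^2$ with (methods − 1) degrees of
freedom; logs strip the order-of-magnitude between-period variation, and
zero totals are excluded from the log fit with a finding.

## Survey geometry and the depth experiment

The UAV's swathe derives from camera geometry: a 20 mm-equivalent lens
frames like a 20 mm lens on a 36 mm-wide full-frame sensor, so the
horizontal field of view is $2\,\mathrm{atan}(36/40) = 84.0°$ and the
sea-surface swathe at 50 m altitude is $2 \times 50 \times
\tan(42.0°) = 90$ m; over the 6.5 km reef track that is 0.585 km².
Quoted *diagonal* fields of view are also convertible
(`horizontal_fov()`), but note they are ambiguous about the aspect ratio
they refer to: the same camera's quoted 94° diagonal reproduces the 90 m
swathe only on the full-frame 3:2 reference (89.2 m), not on the 16:9
video crop (93.5 m) — which is why the lens-equivalence route is the
package default for this derivation. The geometry is flat-water and
nadir-ignoring: no refraction or viewing-angle correction. The boat-based
areas (0.3 km² for the observer's ~30 m swathe, 0.4 km² for the video's
~60 m) are configured constants rather than derived values: the zig-zag
survey track does not reduce to a strip product, and only the UAV area is
exactly forced by its track geometry.

The depth-detectability experiment lowers a plywood turtle model (plain,
then white-marked) at three sites and records the depth at which it stops
being discernible. Depth perception errors are multiplicative, so the
test runs on natural-log depths; the gain is still reported in metres.
The default is the unequal-variance Welch t with fractional
Welch–Satterthwaite degrees of freedom — a reported fractional df (e.g.
3.8) can only arise from the Welch form, so that is the honest default
even where the test is labelled "Student t" — with pooled variance behind
a flag.

## What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions of a large-rookery
programme: six survey periods whose marked cohorts follow the
paint-all-up-to-2000 rule (482–2000) and whose population scale spans the
observed order-of-magnitude range (≈5,000–100,000); three days × two diel
slots; per-survey detection probabilities of 4–8% per method (per-survey
counts at such programmes are a few percent of the estimated population);
a marked-detection odds ratio of 1.6 for the surface observer only,
bracketed by the published SO→UWV and SO→UAV factors (1.53, 1.73);
logit-scale random-effect standard deviations of 0.5 (period), 0.1 (day)
and 0.05 (diel), making between-period variation dominate within-period
variation as repeated surveys of a closed population show; and no
departures.

Two generative choices deserve emphasis:

- **Bias is an odds ratio**, added on the logit detection scale, so
  probabilities stay bounded and κ = 1 means the Lincoln-Petersen
  assumption holds exactly. A consequence worth knowing: at detection
  probability $p$ the realised detection-probability ratio is
  $\kappa/(1 + p(\kappa-1))$, not κ, and over-detection of marked
  turtles also inflates the total count. The exact prediction is
  $E[\hat N]/N = (1 + f(r-1))/r$ with $f = M/N$ and $r$ the realised
  ratio — at the default small detection probabilities this is within a
  few percent of $1/\kappa$, which is what makes the conversion factor an
  estimate of κ, but at $p = 0.15$ the attenuation is material. The
  tests assert the exact prediction, not the approximation.
- **Period-level variation in the marked fraction** enters mainly through
  the marked cohort size, not through detection: a period effect on
  detection shifts marked and unmarked turtles alike and so largely
  cancels in the marked fraction. In the real programme the marked
  fraction varies between periods because nesting numbers (and hence both
  `M` and `N`) vary enormously; recovery tests therefore vary `n_marked`
  per period, and `implied_marked_logit()` returns the exact generating
  values of the fraction model at zero random effects, which is what
  makes posterior-coverage tests sharp.

The generator does not model space (no zig-zag track, no density
gradients along the reef), time-resolved diving/availability, tag loss
(paint persists beyond the survey window), double counting of individuals
within a survey, or observer fatigue. Passing parameter-recovery tests
therefore demonstrates the estimators are correct under the model's own
assumptions — not that real surveys satisfy those assumptions. In
particular the generator implements the missed-unmarked-turtle mechanism
of observer bias only; if real surface observers also double-count marked
turtles, the conversion factor absorbs that too, indistinguishably.

Determinism: every random draw descends from the config seed through
per-(period, day, diel, method) sub-streams, so repeated calls are
byte-identical and adding a method to a design does not perturb the draws
of the others.

## Problem sizes and numerical tolerances

The test suite runs the full pipeline at the study design: 20 seeded
detectability fits at 5000 iterations each for posterior coverage, 200
replicates each for estimator unbiasedness (within 2% of truth) and
conversion-factor recovery (within 10% of the generating odds ratio), and
150 simulated periods for the jackknife-stabilisation summary. The whole
suite completes in about two minutes on one CPU. Detection probabilities
below 1e-9 are clamped with a warning; cumulative pools whose running
marked count is still zero yield `NA` estimates with a warning rather
than infinities; HPD and quantile intervals use sorted draws without
interpolation beyond R's defaults.

## Known limitations

Only the selected nested-intercepts model is implemented; the
random-slope variant (day trend varying by period) is out of scope, as
are open-population models (Jolly–Seber), model averaging, availability
corrections from dive data, and any image analysis. The historical
December series is accepted as user input (`apply_conversion()`) rather
than shipped: only period-level summaries of the modern comparison are
packaged.
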