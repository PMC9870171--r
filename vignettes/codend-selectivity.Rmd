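---
title: "Estimating codend size selectivity from covered-codend data"
author: "codendsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating codend size selectivity from covered-codend data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codendsel)
```

## The statistical model

A covered-codend experiment measures, per haul `j` and 1-cm length class
`l`, the number of fish retained in the codend (`nR_jl`) and the number
that escaped into the fine-mesh cover (`nE_jl`). Conditional on entering
the codend, each fish is retained with a length-dependent probability
`r(l)`, so the class counts are binomial. Because deck time limits how
many fish can be measured, each haul-by-compartment catch is subsampled
at a known ratio `qR_j`, `qE_j` in (0, 1]; measured counts are raised by
`1/q` so the likelihood weights reflect the full catch. Retention is
assumed to vary between hauls, but with few hauls per gear the hauls are
pooled and a single average curve is estimated per gear. The estimation
objective is the raised negative log-likelihood

\[
-\sum_j \sum_l \left\{ \frac{nR_{jl}}{qR_j}\,\ln r(l) +
\frac{nE_{jl}}{qE_j}\,\ln\bigl(1 - r(l)\bigr) \right\},
\]

with `0·ln 0 = 0` and `r` clipped to `[1e-12, 1 - 1e-12]` so that a
degenerate curve against opposing counts yields a huge finite objective
instead of an error. Binomial coefficients are omitted: they are
parameter-free within a dataset, so estimates, likelihood ratios and AIC
*rankings* are unaffected (absolute AIC values are therefore not
comparable across software that keeps them).

## The curve families

Four classical families assume every entering fish contacts the meshes
in a way that gives it a length-dependent chance of escape: Logit,
Probit, Gompertz (two parameters each) and Richards (a third parameter,
the asymmetry `1/δ`). All are parameterised directly by `L50` and
`SR = L75 − L25`:

* Logit: `plogis((l − L50) · 2 ln 3 / SR)` — `2 ln 3 / SR` is the unique
  rate for which the quartile span is exactly `SR`.
* Probit: `pnorm((l − L50) / s)` with `s = SR / (2 Φ⁻¹(0.75))`.
* Gompertz: the Gumbel CDF `exp(−exp(−(l − m)/s))` with `(m, s)` solved
  from the 0.5 and 0.25/0.75 quantiles.
* Richards: the exponentiated logistic `plogis(a + b·l)^(1/δ)`, with
  `(a, b)` solved through the quantile function
  `X(p) = ln(p^δ / (1 − p^δ))`. At `1/δ = 1` it reduces exactly to the
  Logit, which the test suite asserts to 1e-12.

Each family also has a contact variant
`r(l) = 1 − C + C · base(l, L50c, SRc)`: a fraction `1 − C` of entering
fish never makes the kind of mesh contact that permits escape — in a
densely packed codend many fish simply cannot reach the netting — and
those fish are retained regardless of length. That mechanism is exactly
what puts the floor `1 − C` under the curve. For contact models the
parameters `L50c`, `SRc` describe selection *among contacted fish*; the
overall `L50` exists only if the floor is below 0.5 (`SR` only if below
0.25), and `summary()` reports "not reached" otherwise — the standard
situation when a gear retains small fish through congestion rather than
mesh geometry.

Optimisation runs on unconstrained transforms (`L50` free, `log SR`,
`log 1/δ`, `logit C`) so the quasi-Newton search (`stats::nlminb`,
objective tolerance 1e-9 scale) never touches a boundary; results are
always reported on the natural scale. Mixture likelihoods are multimodal,
so fitting starts from a deterministic grid: five `L50` values across the
observed length distribution, `SR ∈ {2, 4, 8}`, `C ∈ {0.3, 0.6, 0.9}`,
`1/δ ∈ {0.5, 1, 2}`, keeping the best optimum. The optimum is verified
against an exhaustive 0.01-cm grid search in the tests.

## Model choice and fit quality

Fits are ranked by `AIC = 2k + 2·nll`; the lowest-AIC converged model is
selected. Fit quality uses the deviance of the haul-pooled raised counts
per length class against the fitted curve, referred to a chi-square with
(occupied classes − k) degrees of freedom; `p > 0.05` is read as an
adequate fit. Raised counts are generally non-integer; the saturated
reference uses the observed raised proportion per class. Overdispersion
(deviance/dof) is reported but never corrected: with few hauls,
between-haul variation commonly inflates the pooled deviance without
implying structural misfit.

One caveat the tests make explicit: the chi-square reference assumes
every counted cell is informative. Length classes where the fitted curve
saturates (`r ≈ 0` or `1`) contribute essentially no deviance yet still
count toward the degrees of freedom, so with a wide length range the
p-value is stochastically high regardless of sample size. The uniformity
property is therefore tested on a population whose lengths keep
retention away from the boundaries; on real wide-range data the deviance
test is conservative.

## Uncertainty: the double bootstrap

Both sources of variation are resampled: the outer stage draws `m` hauls
with replacement (between-haul variation), then the inner stage redraws
each selected haul's *measured* fish with replacement per compartment,
keeping `q` fixed — so subsampling noise propagates — and the model is
refitted. Replicate refits start from the point estimate (bootstrap
perturbations are small, and the full multi-start grid is the fallback
on non-convergence; a replicate that still fails is redrawn, keeping the
population size exact). Confidence intervals are Efron percentiles: the
`k = ⌈n·p⌉`-th order statistics of the replicate population, per length
(on a fixed 0.1-cm grid spanning the observed range ± 2 cm) and per
parameter. No bias correction or studentisation is applied. The whole
population is a deterministic function of one seed.

Two gears are compared by the delta curve `Δr(l) = r_e(l) − r_c(l)`.
Because the two bootstrap populations are generated independently, a
valid bootstrap population for the difference is obtained by pairing
replicate `i` with replicate `i`; percentile intervals of those paired
differences can be no wider than the two marginal intervals combined,
which is what gives the comparison its power. Lengths where the interval
excludes 0 are flagged, and maximal runs of flagged grid points are
reported as significant ranges.

## Codend motion

A shaking codend oscillates vertically; its motion is characterised from
1-Hz records. Definitions: total acceleration is the Euclidean norm of
the three axis readings; the peak-to-peak amplitude is the depth
excursion between consecutive alternating extrema; the amplitude ratio
divides that excursion (cm) by the side-panel length (default 99.6 cm,
the tested codend's measured panel); the period is the time between
successive peaks.

Extremum detection uses topographic prominence with two exposed
parameters: `min_prominence = 0.02` m (the scale of the depth logger's
resolution — smaller wiggles are sensor noise) and `min_separation = 2` s
(same-type extrema closer than two samples cannot represent a real
oscillation at 1 Hz). Flat-topped extrema are timed at the plateau
midpoint (the average of the tied sample times). Peaks and valleys are
forced to alternate strictly, keeping the more extreme member of any
same-type run.

At sea the bottom depth drifts continually, so oscillation statistics
are only computed on stable segments: maximal non-overlapping intervals
(greedy, left to right) whose depth range stays within 0.5 m, lasting at
least `min_duration = 30` s — long enough to hold two oscillations at
the longest period observed at sea (≈ 21 s; the default would need
raising if longer periods were encountered). Records are trimmed by 60 s
at each end (setting and haul-back) or, for flume-tank runs, 300 s at
the start (flow stabilisation). Periods are measured peak-to-peak;
valley-to-valley would be equivalent in expectation and is not offered
separately.

## The synthetic-data generators

`simulate_catch()` emulates the study design: a unimodal length
distribution (discretised normal, mean 22.7 cm, SD 3.5 cm, truncated to
13–40 cm — the observed population profile of the redfish trials), a
known true selection curve (default Logit, `L50 = 20`, `SR = 4`), 10
hauls of 2000 fish, optional between-haul `L50` jitter, and binomial
thinning by the compartment subsampling ratios. For contact models the
two-stage mechanism is simulated explicitly (contact draw, then
length-dependent escape among contacted fish), which the tests verify is
distributionally identical to the mixture curve at `C = 1`. The master
seed fans out to per-haul substreams. `simulate_depth()` generates
`base + drift·t + A·sin(2πt/period) + noise` at 1 Hz, with defaults
emulating the at-sea shaking regime (peak-to-peak 25 cm, period 9.2 s).

What the generators do *not* emulate: length-dependent contact, fish
behaviour (swimming endurance, escape attempts), haul-to-haul changes in
catch volume or towing speed, and any correlation between subsampling
ratio and catch size. Passing tests therefore show that the estimators
recover the truth under the model's own assumptions — not that those
assumptions hold on any particular sea trial.

## Numerical and design choices

* Length classes are 1-cm bins labelled by integer midpoint, fixed
  package-wide (lengths are measured to the nearest centimetre).
* Subsampling ratios apply per haul and compartment; `q = 0` is rejected
  because the likelihood divides by `q`.
* Retention clipping at `1e-12` keeps the objective finite; the
  brute-force oracle in the tests applies the identical clip.
* The bootstrap inner stage resamples the measured-fish list per
  compartment (equivalent in expectation to per-class resampling).
* Efron percentiles use `⌈n·p⌉` order statistics, guarded against
  floating-point excess in `n·p`.
* Degenerate inputs: an all-in-cover (or all-in-codend) dataset fits to
  a flat curve and is flagged `boundary`; non-convergence of every start
  returns a non-converged result object, never a silent answer.

## Problem sizes used in the test suite

The simulation-based properties run at deliberately modest sizes chosen
to make the statistical checks sharp but routine to re-run: parameter
recovery over 100 seeded datasets (10 hauls × 2000 fish each); bootstrap
coverage over 200 outer replicates with 200 bootstrap replicates each
(the reference analyses use 1000 for final inference); delta power over
50 replicate gear pairs and the null rate over 20; the likelihood oracle
over 50 random small datasets. These sizes, and all thresholds, were
fixed in advance of the runs they gate.

## Known limitations

* Pooling hauls estimates an average curve; between-haul random effects
  are not modelled (the generator can produce them, and the bootstrap
  accounts for them in the intervals).
* Absolute AIC values exclude binomial coefficients and are not
  comparable with software that includes them; rankings are.
* The deviance GOF test is conservative when many length classes sit on
  the saturated part of the curve (see above).
* Contact-model parameters are weakly identified with few hauls: `C`
  intervals are wide, and the data cannot distinguish a low floor from a
  long lower tail — a real feature of the design, not an implementation
  artifact.
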