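---
title: "Transient-response features and sensor-array reduction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient-response features and sensor-array reduction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(enose)
```

## The problem

An electronic nose pairs an array of cross-sensitive metal-oxide (MOX) gas
sensors with a pattern-recognition model. Each measurement is a transient:
the array sits in pure air (baseline), the sample's headspace is pumped in
(adsorption, the sensor conductance rises), and pure air flushes it out again
(desorption, the conductance relaxes). The classification task addressed here
is four-way: high-quality wine (HQ), average-quality wine (AQ), low-quality
wine (LQ), and diluted ethanol (Ea), with the additional structure that
samples come in groups — several repeated measurements from the same bottle —
which makes naive cross-validation optimistic.

The package implements the full pipeline: raw-curve handling, a fixed
feature catalogue, group-aware validation, wrapper and filter feature
selection, and the sensor-array reduction experiments. A synthetic-data
generator stands in for the laboratory instrument, so every stage is
exercisable and testable end to end.

## The measurement model behind the generator

The generator emulates a campaign with a 6-sensor array (three sensor types,
two instances of each, paired as slots 1/4, 2/5, 3/6) sampled at 18.5 Hz over
phases of 10 s (baseline), 80 s (adsorption), and 90 s (desorption), and a
cohort of 28 bottles: 5 HQ, 4 AQ, 13 LQ, and 6 Ea, with 10–12 measurements
drawn per bottle.

Kinetics are first-order **in conductance**, not resistance: MOX conductance
is approximately proportional to the surface reaction extent, so

$$G(t)/G_0 = \begin{cases}
1 & \text{baseline}\\
1 + A\,(1 - e^{-t'/\tau_{ads}}) & \text{adsorption}\\
1 + A_{end}\, e^{-t''/\tau_{des}} & \text{desorption,}
\end{cases}$$

continuous at the phase boundary, with $t'$, $t''$ measured from the phase
starts. The stored signal is the resistance $R = 1/G$. The amplitude seen by
sensor $s$ for a sample of class $c$ is

$$A = g_s \cdot a(\mathrm{type}(s), c) \cdot b \cdot (1 + \epsilon),$$

where $g_s \sim \mathrm{lognormal}(0, 0.2)$ is a per-sensor-instance gain
(drawn once per dataset — paired sensors share type kinetics but respond
distinguishably, as real same-series devices do),
$b \sim \mathrm{lognormal}(0, 0.15)$ is a per-bottle concentration factor
(drawn once per bottle — the mechanism behind within-bottle correlation), and
$\epsilon \sim N(0, 0.05)$ is a per-measurement jitter shared across the six
sensors (concentration-like, so one draw per sample rather than per sensor).
Observation noise is multiplicative Gaussian on $G$ (relative sd 0.005), and
amplitudes are floored at $10^{-6}$ so no curve degenerates.

In the **default scenario** the class signal lives in both amplitudes and
time constants. HQ and LQ amplitudes are separated by more than a factor of
two per sensor type; AQ and Ea amplitudes deliberately overlap (their
type-wise means differ by less than one bottle-effect sd), mirroring the
overlap between average-quality wine and ethanol seen in real recordings —
so those two classes are told apart mostly by their slightly different
kinetics. Amplitude values (2.0/3.5/6.0/3.8 for type 1 across HQ/AQ/LQ/Ea,
and proportionally for the other types) were chosen once as plausible
relative conductance rises for alcohol-sensitive MOX devices; they are not
fitted to anything.

Two auxiliary scenarios support the reduction experiments:
`scenario_single_informative_sensor()` confines all class information to
sensor type 1, and `scenario_desorption_only()` makes classes identical in
amplitude and adsorption kinetics, differing only in desorption time
constants. The desorption scenario uses a *balanced* cohort (6 bottles per
class) so that the chance level of an uninformative model is unambiguously
1/4; with the imbalanced default cohort the majority-class baseline (~0.47)
would blur the "at chance" reading. Deliberately not simulated: day-scale
sensor drift, temperature/humidity covariates, and the inter-measurement
purge interval, which carries no data.

## Normalization and segmentation

The baseline reference $R_0$ is the **median** resistance over the baseline
window (robust to acquisition spikes; with a clean baseline it coincides with
the mean). Both normalized views are kept: $r = R/R_0$ and $g = G/G_0 =
R_0/R$. They are deterministic transforms of each other, but features built
from them are not linearly related, and both views earn their keep in
selection.

Segments partition the post-baseline curve: `ads` ends at the sample at or
immediately before the adsorption boundary, `des` starts at the next sample,
and `full` is their concatenation. The baseline window is excluded from all
three — features of a flat reference segment carry no odor information.
Phase boundaries come from metadata, not change-point detection.

## The feature catalogue

Each (sensor, signal, segment) cell yields 23 features; 6 sensors × 2 signals
× 3 segments × 23 = 828. The 23, in fixed order: final value; extremum (max
for a net-positive response, min otherwise); mean; sd; sample skewness;
excess kurtosis; integral; max and min of the exponential moving average of
first differences at α ∈ {0.1, 0.01, 0.001}; max and min of the smoothed
derivative and their times; times to reach 10/25/50 % of the response range;
and the amplitude, time constant, and offset of an exponential fit
$y(t) = c + A e^{-t/\tau}$.

Numerical choices, each with its reason:

* **EMA on first differences** — $y_1 = 0$,
  $y_k = (1-\alpha) y_{k-1} + \alpha (x_k - x_{k-1})$ — is the transient-shape
  transform of the e-nose feature-extraction literature; its extrema capture
  rise/fall dynamics at three time scales. The α triple {0.1, 0.01, 0.001} is
  the canonical spread: at 18.5 Hz these correspond to effective smoothing
  horizons of roughly 0.5 s, 5 s and 54 s.
* **Integral as a left Riemann sum** (`sum(values) * dt`): on the disjoint
  ads/des partition this makes the full-curve integral *exactly* the sum of
  the two phase integrals, a property the test suite asserts at 1e-12.
* **Derivative smoothing**: a centered moving average of 15 samples (~0.8 s
  at 18.5 Hz) before central finite differences — wide enough to kill point
  noise, narrow enough to keep transient peaks. Window edges use truncated
  averages.
* **Crossing times** are linearly interpolated between samples and measured
  from segment start; a zero-range (constant) segment returns the fallback 0
  rather than an error.
* **Exponential fit** by Levenberg–Marquardt with deterministic
  initialization ($c = y_{end}$, $A = y_{start} - y_{end}$,
  $\tau = \mathrm{duration}/3$) and $\tau$ bounded to
  [dt, 10 × duration]. The fit never raises; on solver failure the
  initialization values are the documented fallback. On the composite `full`
  segment a single exponential is of course misspecified — its fitted
  parameters are still well-defined, deterministic shape descriptors, which
  is all a feature needs to be.
* **Skewness/kurtosis** use uncorrected sample moments with an (n−1) sd;
  zero-variance segments yield 0 for both. All fallbacks return finite
  numbers: a feature table never contains NaN/Inf, because downstream model
  training would be poisoned otherwise.

The catalogue size (23 per cell) is the package's load-bearing structural
assumption: the feature families enumerated above, instantiated at these
standard parameter choices, close exactly to the 828-column table the rest
of the pipeline is built around.

## Classification and group-aware validation

The classifier is multinomial logistic regression with an L2 penalty of
strength 1.0 in the summed-log-likelihood convention (the scikit-learn
`C = 1` default; equivalently glmnet's `lambda = 1/n`), on z-scored features
with standardization parameters estimated from the training rows only.

Two validation schemes:

* **LOGO** (leave-one-group-out): one split per bottle; validation is that
  bottle's samples.
* **Group shuffle**: bottles (not samples) are randomly partitioned,
  `round(0.25 · n_groups)` (at least 1) to validation, repeated 100 times by
  default. The 75/25 proportion is applied at the *group* level because that
  is the only reading that guarantees the never-split-a-bottle restriction
  for every cohort.

Per-repeat split seeds are derived from the master seed by a deterministic
arithmetic map, so split *r* is identical no matter how many repeats are
requested. Whether features should be standardized before the fit is exposed
as a config flag (default on).

An implementation note a maintainer should know: the inner fitting routine
for narrow models (p ≤ 60) is a direct damped-Newton solver for the exact
ridge-penalized multinomial likelihood, written in compiled code, because
wrapper selection at study scale requires on the order of 10^5 model fits
and per-call overhead dominates otherwise. Wide models delegate to glmnet at
the equivalent penalty along a short warm-start path. Both engines optimize
the same objective; the test suite asserts prediction agreement with glmnet
on shared cases. A behavioral consequence of ridge strength 1.0 worth
knowing: on a *single* ordinal feature with few samples of a middle class,
the penalty can collapse that class's decision interval — a property of the
model, not a bug, and the reason some tests of "perfect-feature" behavior
use a weak penalty to isolate the machinery being checked.

## Feature selection

**Recursive forward selection** (wrapper): step 1 cross-validates every
single feature and keeps the best; step k+1 tries every unchosen feature
appended to the current set. Ties break deterministically by column order,
so the only stochastic ingredient is the split seed — by design, the
run-to-run variability of selected sets then stems from cross-validation
randomness alone, matching the observation that different seeds select
different but similarly performing sets. The whole procedure can be repeated
over several outer seeds (default 5) and averaged. The inner repeat count
defaults to 25 rather than 100: each step scores hundreds of candidates, and
the inner estimate only needs to *rank* them; the final reported accuracy of
a chosen set should come from an independent, full-repeat cross-validation.

**Filters**: Fisher score (between/within class variance ratio, (n−1) class
variances, zero denominator scores 0); mutual information (plug-in, in bits,
on deterministic quantile bins, default 8 — chosen over nearest-neighbor MI
estimators for exact reproducibility, with the bin count exposed); and
multi-class ReliefF (Manhattan distance on min-max-scaled features, k = 10
neighbors, miss contributions weighted by class prior, all n instances used
in deterministic row order rather than sampled — eliminating the method's
one conventional randomness source). Filter ties break by feature-id string.

## Experiments

`sensor_subset_experiment()` cross-validates all 63 nonempty sensor subsets;
`single_sensor_sweep()` runs forward selection within each sensor;
`source_restricted_selection()` restricts the pool by signal (R/G) and/or to
the adsorption segment (the ALL / ALL-G / ALL-R / ON / ON-G / ON-R named
restrictions); `wrapper_vs_filter_experiment()` compares the forward-selected
prefix with each filter's top-k at matched k; `pca_view()` projects samples
onto the leading principal axes of selected features for visual inspection
of class structure. `run_full_study()` chains everything into a reproducible
report bundle (CSV/JSON, optional figures), with a `full_scale` flag that
restores 100 inner repeats × 5 outer seeds; its default runs are scaled down
(25 inner repeats, 2 outer seeds) — problem sizes chosen so a complete study
on the default scenario finishes in minutes on a laptop while leaving the
qualitative conclusions unchanged.

Filter rankings in the comparison are computed once on the full table, as is
conventional for filter methods in this setting; their accuracies at top-k
are therefore mildly optimistic relative to rankings recomputed inside every
fold — a known, accepted asymmetry that favors the filters, which makes the
wrapper-beats-filters finding conservative.

## What the synthetic tests do and do not show

Passing tests on generated data demonstrate that the pipeline recovers
structure the generator put in: class labels from kinetic/amplitude
patterns, within-bottle correlation handled by group-aware splits, the
desorption phase's information content, concentration of signal in one
sensor. They do not certify performance on real recordings — real MOX data
add drift, humidity and temperature effects, non-first-order kinetics, and
chemical interferents the generator does not model. The accuracy numbers
printed by the acceptance machinery are properties of the synthetic
scenarios under their documented seeds, not reproductions of any published
measurement.

## Known limitations

* The exponential is the only analytic fit family; sigmoid/polynomial fits
  and moving-window capture features are not implemented.
* Backward elimination, genetic-algorithm search, and multivariate filters
  (Wilks' Λ, Mahalanobis) are out of scope.
* The classifier is the single model the study design calls for; there is no
  model-comparison harness.
* Phase boundaries must be supplied; there is no change-point detection.
* ReliefF materializes the full n × n distance matrix — fine for cohorts of
  hundreds, wasteful beyond a few thousand samples.
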