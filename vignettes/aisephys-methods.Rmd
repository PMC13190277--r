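---
title: "Methods: models, parameters and design choices in aisephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in aisephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aisephys)
```

`aisephys` quantifies axon-initial-segment (AIS) structure and intrinsic
neuronal excitability from current-clamp recordings, fluorescence line
profiles and serial lesion sections, and compares experimental groups with
bootstrap estimation statistics and Bayesian hierarchical models. This
vignette is the package's account of its science: what each stage computes,
the assumptions behind it, which knobs matter, and where genuinely open
design decisions were resolved.

## Electrophysiological feature definitions

All stages share one unit convention — mV, pA, ms (reported), MΩ, pF, µm,
mm³ — chosen so the capacitance relation is dimension-exact:
$C\,[\mathrm{pF}] = 1000\,\tau\,[\mathrm{ms}]/R_\mathrm{in}\,[\mathrm{M\Omega}]$.

**AP threshold** is the membrane potential at the last upward crossing of a
depolarisation-rate criterion of 10 V/s before the spike peak. The
acquisition convention (50 kHz sampling) makes the numerical details mild:
dV/dt is computed by central differences at the native rate, the crossing is
searched backward from the peak within a 5 ms window, the latest crossing
wins, and the crossing is linearly interpolated between samples. The search
window, criterion and interpolation scheme are declared defaults
(`default_config()`), not values inherited from any particular acquisition
system; at 50 kHz higher-order interpolation changes thresholds by far less
than the electrode noise floor.

**AP amplitude** is peak minus threshold; **AP half-width** is the time
between the interpolated upward and downward crossings of
threshold + amplitude/2. Both are invariant to adding a constant to the
whole sweep; the threshold shifts by exactly that constant (a property the
test suite asserts).

**RMP** is the mean of a 100 ms pre-stimulus baseline. The source
definition — "potential at the start of the recording" — names no window;
100 ms is this package's documented default.

**Input resistance** is the OLS slope of the steady-state voltage
deflection (mean of the final 100 ms of each 1 s step) against injected
current over the −25..−100 pA hyperpolarising family, converted to MΩ.
Steady-state windows make the estimate independent of the membrane time
constant.

**Membrane time constant** comes from a Levenberg–Marquardt fit of
$V(t) = y_0 + A e^{-(t - X_0)/\tau}$ to the charging phase, with $X_0$
fixed at step onset, the first 2 samples after onset skipped (pipette
transient), and a window of 5 estimated time constants, re-estimated once
from the first fit. Initialisation is deterministic ($y_0$ = steady-state
mean, $A$ = onset-minus-steady difference, $\tau$ = time to 63% of the
deflection), so fits are reproducible without random restarts.
Non-convergence and degenerate (flat) traces return a flagged result, never
an exception. Whether the original analysis pooled the four hyperpolarising
steps or fitted one is not stated; the per-cell wrapper
(`passive_result()`) fits each step and averages the converged estimates.

**Rheobase** is the smallest step amplitude evoking at least one spike,
averaged over the two protocol repeats. **Evoked firing frequency** is the
spike count per 1 s step (counts over 1 s are Hz), averaged over repeats.
**Maximum firing frequency** is read as the maximum over steps of that
whole-step mean rate, consistent with the per-step definition; the
alternative instantaneous reading (reciprocal minimum ISI) is exposed via
`max_firing_frequency(definition = "inv_min_isi")` because the source
wording does not adjudicate. Series-resistance QC excludes recordings whose
series resistance changes by more than 20% (boundary passes).

## AIS morphometry

AIS boundaries use the 0.33-of-maximum rule: the start is the first upward
crossing and the end the last downward crossing of 0.33 × the maximum of
the (smoothed, baseline-subtracted) profile, linearly interpolated.
Three details are under-determined by the rule and resolved here:

* **Baseline.** A relative threshold is ill-posed on a non-zero
  background, so the threshold is applied to the profile minus the median
  of the flanking 10% of samples at each end of the trace.
* **Smoothing.** A 1 µm moving average precedes the maximum and the
  crossings (window configurable; 0 disables it). On noiseless profiles
  smoothing is unnecessary and slightly biases edges, which is why the
  analytic trapezoid checks run unsmoothed.
* **Multiple excursions.** Dips below threshold between the first rise and
  last fall are bridged — the literal first/last reading.

The detector is exactly invariant to positive intensity scaling. Distance
from soma is the signed difference between the AIS start and the soma end
on the same trace, with negative values flagged as label overlap. Per-cell
measures aggregate to one mean per animal × hemisphere × layer stratum,
the unit of analysis for group statistics.

Lesion volume is $\sum_i a_i \cdot t \cdot s / 10^9$ mm³ for traced areas
$a_i$ (µm²), thickness $t = 30$ µm and series factor $s = 3$ (every third
section traced). Dimensional analysis fixes the $10^9$ divisor (µm³→mm³).
For polyline geometry the 3D path length always dominates its 2D
projection (`compare_projection_length()`); empirical reports of the
reverse with projection-based measurements stem from pixel-aggregation
effects during flattening that pure polyline geometry does not model, so
no invariant is asserted in that direction for images.

## The synthetic-data generators

The generators define the study conditions for every recovery test.

* **Passive sweeps** follow the RC closed form
  $V(t) = E_L + I R (1 - e^{-t/\tau})$ with defaults $E_L = -70$ mV,
  $R_\mathrm{in} = 150$ MΩ, $\tau = 20$ ms — mid-range values for cortical
  pyramidal neurons — and i.i.d. Gaussian recording noise.
* **Spiking sweeps** are leaky integrate-and-fire, integrated with the
  exponential-Euler update at the sampling grid (exact for
  piecewise-constant current, so the integration scheme contributes no
  error at any rate). At threshold a piecewise-linear AP template is
  painted in: linear rise (0.2 ms) to 100 mV above threshold, linear fall
  (0.6 ms) back **to threshold**, then a linear descent to the reset over
  the remaining refractory period. Ending the fall at threshold rather
  than at reset is deliberate: it gives the template the closed-form
  half-width $(t_\mathrm{rise} + t_\mathrm{fall})/2$ that the feature
  oracles rely on, while the reset is still reached by the end of the
  refractory period. Template durations are quantised to the sampling grid
  and the effective values recorded in the ground-truth attribute, making
  the oracles exact on the sampled trace. The rise slope is validated
  ≥ 50 V/s so the 10 V/s detector lands within one sample of the true
  threshold.
* **Threshold comparison tolerance.** A step whose steady state sits
  exactly at threshold (the grid-rheobase case, e.g. 250 pA for a 25 mV
  threshold depth over 100 MΩ) approaches threshold asymptotically; in
  floating point the trajectory stalls a few ulp below the fixed point and
  would never fire. The simulator therefore compares against
  $V_T - 10^{-6}$ mV (configurable), which makes the measured grid
  rheobase equal the long-step closed form without affecting any
  physically distinct stimulus.
* **Recording noise** is added to the emitted samples, not to the
  dynamics, so spike counts are deterministic given the model. This
  emulates measurement noise; it does not emulate channel noise,
  adaptation, depolarisation block or biophysically detailed AP shapes —
  so passing recovery tests demonstrate correctness of the measurement
  code under the stated model, not robustness to every pathology of real
  recordings.
* **AIS profiles** are trapezoids with analytic 0.33-crossings
  (length $=$ plateau $+ 1.34\,\times$ edge at zero baseline) plus
  Gaussian noise; real Ankyrin-G profiles are not trapezoidal, but the
  boundary rule only consumes level crossings, which the trapezoid probes
  directly.
* **Cohorts** are balanced factorial designs: 3 animals per Group × Sex
  cell (12 animals — six per group, evenly split by sex, matching the
  electrophysiology cohort sizes) and 2 cells per Hemisphere × Layer
  stratum per animal. Outcomes are generated on a declared scale as
  design effects plus correlated animal-level intercept/hemisphere-slope
  effects (SDs 1 and 0.5, correlation 0) plus residual noise (SD 2),
  magnitudes in the millivolt range typical of AP-threshold outcomes.
* **Lesion series** invert the volume formula across sections with an
  elliptical axial profile and seeded jitter, rescaled so the round trip
  is exact.

## Estimation statistics

`unpaired_mean_difference()` reports the raw difference in means (oriented
comparison − reference, i.e. stroke − sham and GFP+ − GFP−) with a
percentile bootstrap interval over 5000 within-group resamples by default.
Percentile intervals are the default because the upstream toolchain's
interval type is not documented in the source; BCa is available as a
config switch and implemented with jackknife acceleration. Intervals are
deterministic given a seed. At the study's n≈20 the percentile interval is
mildly anti-conservative (null exclusion near 6% rather than 5%), which
the calibration suite verifies stays inside 5% ± 2%.

## Bayesian hierarchical models

The group models are Gaussian hierarchical linear models on the
(optionally log- or log1p-transformed) outcome with the full
Group × Hemisphere × Sex × Layer factorial and a correlated random
intercept and hemisphere slope per animal. Sampling is by MCMC in JAGS;
seeds drive the per-chain generators so posterior summaries are
reproducible.

Priors follow the published specification where it is stated: Normal(0, 5)
on fixed effects, half-Student-t(3, 0, 2.5) on group-level SDs. Two gaps
are filled as the package's own choices:

* **Intercept.** A Normal(0, 5) prior on the intercept of an outcome
  centred at, say, −44 mV would be sharply informative. The intercept
  instead gets Student-t(3, median(y), 10·sd(y)) — the separate-intercept
  convention of standard Bayesian regression software — and Normal(0, 5)
  applies to the non-intercept coefficients.
* **Residual SD and correlation.** Half-Student-t(3, 0, s_y) with s_y the
  sample SD of the transformed outcome, and a uniform prior on the
  intercept–slope correlation.

Estimated marginal means average the linear predictor, per posterior draw,
over the balanced grid of the factors not conditioned on (equal weights;
random effects marginalised at zero; any current basis held at its sample
mean), then back-transform (exp or expm1) before summarising, so response-
scale EMMs are order-consistent with the link scale. Directional
hypothesis tests report posterior odds — the fraction of draws on the
hypothesised side of zero against its complement — categorised by the
conventional cut-offs (≤1 none, ≤3 anecdotal, ≤10 moderate, ≤100 strong,
>100 extreme; boundaries fall to the lower band, and a printed cut-off
table whose last line contradicts its neighbour is read as BF > 100 =
extreme). Whether published "evidence ratios" divide out prior odds is not
stated; posterior odds are implemented and labelled as such. When every
draw is on one side the ratio is reported capped at the draw count rather
than as a sharp number.

For the current-adjusted evoked-firing analysis, the current-independent
model adds a shared piecewise-linear spline in current (fixed quantile
knots) to the factorial on log1p(frequency); the current-dependent model
crosses the factorial with a degree-2 orthogonal polynomial in current.
The shared-curve basis is deliberately a fixed-knot linear spline rather
than a thin-plate basis: the modelling intent (a flexible shared I-F
shape) is identical, and the basis is reproducible without any one
package's spline construction. Model comparison uses WAIC computed from
the pointwise posterior log-likelihood with the standard error of the
pointwise elpd difference; differences within one SE are reported
indeterminate. Marginal-likelihood Bayes factors via bridge sampling were
not reimplemented because they are not reproducible without the exact
original basis and priors; WAIC answers the same model-preference question
with a declared, checkable criterion.

### Problem sizes and sampling scale

Routine fits use 4 chains × 2000 iterations (500 warmup); the
publication-scale protocol (4 × 50 000, 10 000 warmup — 160 000 retained
draws) is a configuration choice, not a code path difference. The
calibration suites run 1000 null bootstrap datasets (n = 20 per group,
2000 resamples), 100 simulated cohorts for pooled 90% credible-interval
coverage, and 50 replicates for recovery of a declared −0.70 mV group
effect, each fit at 2 chains × 2500 iterations. These sizes give binomial
standard errors comfortably inside the acceptance bands while keeping the
suites at desk scale.

## Known limitations

* The LIF template has no after-hyperpolarisation, adaptation or
  depolarisation block; feature extraction is validated against its
  closed forms, not against biophysical diversity.
* The image sampler assumes single-channel maximum projections and manual
  polylines; no automated tracing or 3D deconvolution is provided.
* Gaussian residuals are assumed throughout the hierarchical models
  (transformations are the lever for skew); non-Gaussian likelihoods are
  out of scope.
* JAGS mixing on the random-slope SD is slow at small animal counts;
  Rhat > 1.01 on any monitored parameter flags the result `unreliable`
  rather than silently passing it downstream.
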