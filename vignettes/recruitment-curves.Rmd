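---
title: "Modelling MEP recruitment curves with mepkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MEP recruitment curves with mepkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepkit)
```

This vignette is the package's account of its science: the data model it
assumes, the sigmoid it fits and why it is parameterized the way it is, the
numerical choices behind the filters, the screening heuristic, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where more than one defensible choice existed.

## The data model

A **session** is every sweep recorded while building one recruitment curve
under one experimental condition: a numeric array in canonical
`[samples × channels × sweeps]` order, annotated with a strictly ascending
vector of stimulation intensities, the number of trials recorded at each
intensity (counts may differ between intensities — storage stays a flat
sweep axis with cumulative-sum offsets), and the sampling rate. Sweeps are
assumed sorted by ascending intensity with trials contiguous;
`reorder_by_intensity()` restores that order for randomized acquisitions
with a stable sort, so equal intensities keep acquisition order. Sample
indexing is 0-based and epoch windows are half-open `[start, stop)` in
milliseconds relative to sweep onset, where onset is the end of
stimulation (acquisition systems typically trigger frames there).

A **record** is one subject's ordered list of sessions; the first session
is *always* the baseline condition — this is a structural convention, not
a flag, so downstream comparisons cannot silently pick the wrong
reference. A **master** groups records that share a condition sequence and
refuses records with unequal session counts, which is what makes
per-condition aggregation across subjects well defined.

Sessions, records and masters serialize as plain JSON (records and
masters as small manifests referencing session containers by relative
path). The choice of diffable text over a binary container is deliberate:
annotation is the most error-prone manual step in this workflow, and text
manifests make it reviewable. Proprietary acquisition formats are out of
scope by design; acquisition software exports to open containers first.

## Quantifying epochs

Four per-epoch metrics are provided, all operating on the uniformly
sampled trace `f(t)` cut from a sweep by the epoch window:

* **AUC** `= ∫|f|dt` by the trapezoidal rule, in signal·seconds.
* **RMS** `= sqrt(∫f² dt / (T₂−T₁))`, with the integral also trapezoidal.
  Using the same quadrature for both keeps the classic relation
  `RMS ≥ AUC/duration` (Jensen's inequality) exact at the discrete level,
  with equality only for constant-magnitude signals; the tests assert this
  as a one-sided bound on random epochs.
* **Peak-to-peak** `= max f − min f` on the raw trace; invariant to
  additive offsets, so baseline level does not leak into it.
* **Latency**: the first time the rectified trace reaches
  `base + pct/100 · (max|f| − base)`, where `base` is the mean rectified
  amplitude over a leading window (default 2 ms). The baseline-referenced
  form was chosen over thresholding a raw percentage of the maximum; the
  rectified trace is used so negative-going onsets are detected. One
  consequence worth knowing: because the threshold never exceeds the
  attained maximum, a crossing always exists, so latency is always defined
  for finite data. Latency does not follow a sigmoidal stimulus–response
  profile, so recruitment curves are never fitted to it; the pipeline
  routes latency sessions to the direct mean-comparison path instead.

Per-intensity summaries are plain arithmetic means over surviving trials —
no trimming or winsorizing, since outlier handling belongs to the explicit
screening step, not to the summary statistic.

## The sigmoid and its gauge

The recruitment curve is modelled as

$$y(x) = P + \frac{M-P}{1 + Q\,e^{-e^{L}(x-K)}}$$

with lower asymptote `P` (sub-threshold response floor), upper asymptote
`M` (saturation), logarithmic slope `L` (the growth rate per intensity
unit is `exp(L)`, so any real `L` yields a positive rate), centre `K`, and
a positive shape offset `Q` that is set from the data and never optimized
— four free parameters. A Gompertz-style reading of the growth term (a
double exponential) would also be S-shaped; the generalized logistic was
chosen because it keeps the four-parameter structure with `Q` as a pure
offset and admits closed-form inversion,

$$x = K - \log\!\left(\frac{M-P}{Q\,(y-P)} - \frac{1}{Q}\right) / e^{L},$$

which the curve-comparison metrics rely on.

`K` and `Q` are not separately identifiable: `Q e^{-r(x-K)} =
e^{-r(x-K')}` with `K' = K - \log(Q)/r`. Fixing `Q` from the data
therefore chooses a *gauge*, and the raw `K` of two fits with different
`Q` are not comparable. Every fitted curve consequently reports its
`midpoint` — the intensity at half-maximum, `K + log(Q)/exp(L)` — which is
gauge-invariant and is what the tests (and any cross-fit comparison)
should use for horizontal position.

## Fitting procedure

Initial estimates come from order statistics: `P₀`/`M₀` are medians of
5-value windows centred on the nearest-rank 5th/95th percentile positions
of the sorted responses (windows clipped at the vector ends; the median of
an even clipped window is the mean of its central pair), `K₀` is the mean
of the two intensities whose responses sit closest to `(P₀+M₀)/2`, and
`L₀` comes from the steepest discrete slope via the logistic identity
`max dy/dx = exp(L)(M−P)/4`. Flat data (`M₀ ≤ P₀`) take a degenerate path
— all level parameters at `mean(y)`, zero slope — and still run through
the optimizer so the stopping machinery is exercised rather than
special-cased. `Q` is the response at the lowest intensity (floored at
`1e-6`); pass `q = 1` for a standard logistic gauge.

Fitting minimizes the scale-free error `RMSE/(max y − min y)` (plain RMSE
for constant data — the only case where the range is zero). The responses
are range-normalized *before* optimization and `P`, `M` mapped back
afterwards, which makes the entire procedure exactly equivariant under
rescaling of the response units; without this, the data-derived `Q` gauge
made the optimizer's trajectory unit-dependent even though the error
metric was not.

Optimization proceeds in **cycles**: each cycle runs a Nelder–Mead simplex
(base R `optim`) from the current best parameters to local convergence,
and after every cycle three stopping rules are checked in strict
precedence:

1. error below the tolerance (default **0.1**) — also checked before the
   first cycle, so an arbitrarily loose tolerance returns the initial
   estimates unchanged;
2. a strictly positive improvement smaller than the stall delta
   (default **0.01**);
3. **10** consecutive non-improving cycles (the counter resets on any
   strict improvement).

The delta rule fires only on *positive* improvements below threshold;
zero-improvement cycles feed the 10-counter. Under the alternative reading
(any |Δ| < 0.01 stops), rule 3 could never fire, since a non-improving
cycle would always trip rule 2 first. If the fit stalls (rule 2 or 3) with
the error still above tolerance, one deterministic restart from perturbed
parameters (`K`, `L` × 1.1) is attempted and kept if it helps. The
iteration granularity — simplex-to-convergence cycles rather than single
simplex moves — matters: per-move stopping with these thresholds halts
after a handful of moves with parameters far from the optimum, which is
measurably incompatible with recovering known synthetic parameters.

Goodness of fit is `R² = 1 − SS_res/SS_tot` (1 when data are constant and
residuals vanish; undefined when data are constant but residuals are not).
After fitting, a **saturation check** regresses a line through the last
three per-intensity means, with responses normalized by the session
maximum and intensities by the median intensity step so the slope is
dimensionless; the curve saturates iff that slope is strictly below 0.2.
A non-saturated curve raises a warning — never an error — because the
judgement of whether an incomplete curve is still usable belongs to the
experimenter. The slope is computed in centered closed form
(`Σxc·y / Σxc²`) rather than through a general regression routine so the
strict boundary comparison is not blurred by unnecessary rounding.

## Preprocessing choices

The band-pass is a Butterworth design (maximally flat passband) applied
zero-phase — forward and backward — so MEP onset latencies are not
distorted; effective attenuation consequently doubles in dB. Defaults are
5–600 Hz, off unless enabled: clean epidural/indwelling recordings rarely
need it, and filtering by default would quietly alter amplitudes. Order
selection uses `signal::buttord` with ≤ 4 dB passband ripple and ≥ 30 dB
stopband attenuation; since order selection needs stopband *edges* and the
passband edges alone do not determine them, they are set at `0.5·low` and
`min(1.25·high, 0.98·Nyquist)`. Two numerical points:

* High-order IIR filters expanded into a single polynomial are numerically
  unusable at low normalized cutoffs (a 5 Hz edge at 5 kHz puts poles
  within ~10⁻³ of `z = 1`; the expanded form was measured to amplify
  rather than filter). The band is therefore realized as a high-pass ∘
  low-pass cascade of first/second-order sections computed from the
  closed-form Butterworth poles plus bilinear transform.
* Edge transients are handled by odd-reflection padding with steady-state
  section initialization, so a constant input produces (numerically) zero
  high-pass output from the first sample.

The mains notch is a cascade of RBJ second-order notch biquads at
`60·k` Hz, `k ≤ 6`, each applied zero-phase; the quality factor defaults
to 30 (≈ 2 Hz bandwidth at 60 Hz), wide enough to remove mains ridge and
narrow enough to leave 35 Hz untouched within 1 dB. Whole sweeps are
filtered *before* epoch extraction so the analysis window never sits on a
filter edge.

## Screening

Artifact handling is deliberately manual: the package renders per-trial
heat maps (`heatmap_matrix()`, `plot_heatmap()`) and suggests candidates
(`suggest_outliers()`), but only `remove_trials()` — an explicit user call
— ever deletes anything, and it refuses to empty an intensity entirely.

The suggestion heuristic is a robust z-score: a trial's deviation from its
intensity's median, in units of a pooled scale estimate. With typical
trial counts (5–10 per intensity) a *within*-intensity MAD is far too
unstable to threshold — measured on Gaussian null data, thresholding
per-intensity MAD z-scores at 5 flagged something in roughly two-thirds of
clean 9 × 5 sessions. The pooled estimator divides each absolute deviation
by a per-group-size consistency constant (the median absolute deviation
from the sample median of a standard normal sample of that size,
Monte-Carlo calibrated, 4×10⁵ replicates per size) and takes the median
across all assessable intensities; the same null scenario then flags ~1 %
of clean sessions while a 50× artifact remains unmissable.
Single-trial intensities are skipped — there is nothing to deviate from.

## The synthetic generator

`generate_session()` emulates the geometry of a stimulation experiment:
each sweep is a 300 Hz sinusoid under a 1.5 ms-SD Gaussian envelope (a
Morlet-like wavelet — chosen because its peak-to-peak, AUC and RMS have
closed forms that oracle tests can check) placed at a 10 ms onset with
Gaussian latency jitter, and scaled so the *realized* peak-to-peak
amplitude equals the ground-truth sigmoid at that sweep's intensity plus
Gaussian amplitude noise (floored at zero). Optional 60 Hz line noise, a
slow half-sine baseline drift and white background noise can be
superimposed, and `inject_artifact()` corrupts a chosen trial the way
motion or interference would. Defaults mirror a typical rodent cortical
stimulation setup: 5000 Hz sampling, intensities from 0.5 mA in 0.5 mA
steps, 10 trials per intensity, 50 ms sweeps, amplitude noise at 5 % of
the upper asymptote. Noise is modelled on the *amplitude* rather than as
independent per-sample noise because per-sample noise biases extreme-value
metrics (peak-to-peak picks up the maximum of the noise), which would
confound amplitude-recovery oracles; per-sample noise is still available
via `background_sd` for tests that need it.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: motor-unit physiology (the amplitude–
intensity relation is imposed, not emergent), trial-to-trial waveform
shape variability, heteroscedastic noise that grows with MEP size,
electrode drift across a session, or correlated noise between channels.
Parameter-recovery results on synthetic sessions bound the pipeline's
algorithmic error, not its robustness to every physiological nuisance.

All randomness flows from one seeded generator with a fixed draw order
(all amplitude draws, then all jitter draws, then background), so a seed
reproduces a session bit for bit and toggling one noise component does not
reshuffle the others. The caller's RNG state is saved and restored.

## Curve comparison and aggregation

Three metrics compare a record's curves against its baseline:

* **MEP metric** (vertical cut): `m%` of the baseline's upper asymptote
  defines a target response; inverting the baseline gives the cut
  intensity; every curve is evaluated there. Reported as percent of
  baseline (baseline ≡ 100); an `as_change` switch emits `value − 100`
  instead, for readers who prefer percent change.
* **Stimulation metric** (horizontal cut): the cut response is the
  baseline's value at `s%` of the baseline session's maximum intensity
  (the baseline span, not per-condition spans, anchors the reference);
  each curve is inverted to find the intensity reaching it. Curves whose
  asymptote lies below the cut get an `NA` marker plus a warning rather
  than an error, so group summaries degrade gracefully.
* **Slope metric**: a smooth sigmoid has no exactly-linear segment, so the
  "linear portion" is operationalized as the contiguous dense-grid region
  (containing the steepest point) where the derivative stays ≥ 90 % of its
  maximum (fraction configurable); the slope is the regression slope over
  that region, optionally normalized by the baseline slope (baseline ≡ 1).

Default cut percentages are 50 (the MEP50/Stim50 conventions).
`group_aggregate()` averages normalized values across records per
condition and reports the standard error (sample SD over √n); undefined
markers are excluded and counted, and a single record yields an `NA`
standard error rather than a fabricated zero. `direct_mep_comparison()`
covers the no-curve workflow: pooled trial means ± SE per condition,
no fitting involved.

## Problem sizes and numerical conventions

The test-suite scenarios use 9 intensities × 5 trials (the screening and
recovery scenarios) and 6 × 10 (annotation arithmetic), 250-sample sweeps
at 5000 Hz, 20-seed recovery batches, 60-replicate screening batches and a
60-curve noisy-recovery batch; the whole suite runs in a few seconds.
Tolerances that matter: fit tolerance 0.1 and stall delta 0.01 on the
scale-free error; `Q` floored at `1e-6`; inversion targets must lie
strictly inside the open asymptote interval; dense curves default to 200
points spanning exactly the session's intensity range. Ties in
`reorder_by_intensity()` preserve acquisition order; trial removal always
removes whole sweeps across channels (per-channel removal would desynchronize
the annotation, and multi-muscle analyses re-quantify per channel anyway).

## Limitations

Only the sigmoid family is fitted — data that genuinely follow another
shape (e.g. non-monotonic facilitation/suppression profiles) should be
quantified and exported for custom modelling rather than forced through
`fit_recruitment()`. No inferential statistics are computed across
conditions; the bundle's bar data (means, SEs, ns) are inputs to whatever
testing framework the study design calls for. Confidence intervals on the
fitted parameters are not provided. Proprietary acquisition files are not
parsed. The latency metric's baseline-referenced threshold means a
"never crossed" outcome cannot occur; if a hard undefined marker is needed
(e.g. absent responses at sub-threshold intensities), screen by amplitude
first.
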