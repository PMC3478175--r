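---
title: "Neuronal avalanche analysis: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuronal avalanche analysis: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(avalanchr)
```

## The analysis in one paragraph

A neuronal avalanche is a cascade of negative local field potential
(nLFP) events that spreads across electrodes in consecutive time bins
and ends at a blank bin. If the underlying cortical network operates
near a critical branching point, the distribution of avalanche sizes
$s$ (active electrodes summed over the cascade's bins) follows a power
law $P(s) \propto s^{\alpha}$, and the exponent $\alpha$ — estimated as
the slope of a straight line fit to $\log_{10} P(s)$ versus
$\log_{10} s$ — summarises the network state. `avalanchr` implements
detection, binning, extraction, fitting, shuffle-surrogate validation
and group comparison, together with a branching-process generator whose
exact size law is known in closed form, so the whole chain is testable
against analytic ground truth.

## The generative model

`simulate_branching()` runs a discrete-time branching process on the
4 ms frame grid. Cascades are seeded by a Poisson process with rate
`seed_rate` (events/s across the whole array); every event active in
frame $t$ spawns a $\mathrm{Poisson}(\sigma)$ number of offspring events
in frame $t+1$. The branching parameter $\sigma$ is the control
parameter: $\sigma = 1$ is the critical point, $\sigma < 1$ subcritical.

The offspring law is Poisson deliberately: the total progeny of a single
cascade then follows the Borel distribution

$$P(S = s) = \frac{e^{-\sigma s} (\sigma s)^{s-1}}{s!},$$

implemented in log space by `borel_pmf()`. This closed form is the
package's analytic oracle — the test suite checks that simulated size
distributions converge to it, that its critical tail exponent is
$-3/2$, and that the log–log fit over sizes 1–10 of the critical law
lands near $-1.47$ (slightly steeper than $-3/2$ because the asymptotic
regime is not yet reached at $s \le 10$).

Two simulator modes exist because two different questions do:

* **unconstrained** — offspring are abstract events; isolated cascades
  are exactly Borel. Used for oracle-grade runs. Critical cascades have
  infinite mean size, so a cascade reaching $10^4$ events is terminated
  and flagged `truncated`; this affects only the extreme tail, never
  the fitted range 1–10.
* **mapped** — every event lands on a uniformly chosen electrode of the
  `n_channels` grid and an electrode counts at most once per frame,
  matching the per-channel-per-frame semantics of detection. Activity
  saturates at the grid size, which is why supercritical $\sigma$ is
  allowed here but rejected (above 1.3) in unconstrained mode.

Seeds arriving while a cascade is still active merge into the same
avalanche, exactly as blank-frame extraction would see them. At the
session default (`seed_rate = 20`/s, 0.08 expected seeds per frame)
merging is common enough to bias a comparison against the pure Borel
law by a few percent; oracle runs in the tests therefore seed sparsely
(1–2/s), where the merge probability is negligible. This is a property
of the model, not an artifact: overlapping cascades are merged in real
recordings too.

## Rendering and detection

`render_lfp()` turns a raster into continuous traces: each event is an
inverted-Gaussian deflection (default depth 80 µV, full width 20 ms,
SD = width/6) added to independent per-channel Gaussian noise that is
band-limited to 10–200 Hz and rescaled to `noise_sd_uv` (default
10 µV, i.e. 8× SNR). The template's width keeps it inside the 10–200 Hz
passband, so rendering followed by detection round-trips.

Detection mirrors the standard nLFP procedure: zero-phase band-pass at
10–200 Hz, then per-channel threshold crossings below $-k \cdot SD$
with $k = 4$. Two details deserve explanation:

* **Filter realization.** The band-pass is the exact magnitude response
  of a forward–backward 4th-order Butterworth, applied in the frequency
  domain. Time-domain transfer-function filtering of a 10–200 Hz band
  is numerically ill-conditioned at high sampling rates (at 40 kHz the
  normalized low edge is $5 \times 10^{-4}$ and recursive filtering
  diverges); the frequency-domain form is exact at any rate, has
  strictly zero phase (event timing is never lagged), and removes DC
  identically. The cost is circular edge handling, irrelevant at
  session lengths of many filter time constants.
* **SD of basal activity.** The default estimator is the scaled median
  absolute deviation (robust to contamination of the trace by the very
  events being detected); the plain sample SD is available as
  `sd_estimator = "global"` for sensitivity analysis. No baseline
  window is assumed.

Event time defaults to the threshold-crossing sample. For applications
needing the deflection center (e.g. validating timing against ground
truth), `time_at = "trough"` locates the event as the depth-weighted
centroid of the below-threshold excursion computed on a
Gaussian-smoothed copy of the trace (`trough_smooth_ms`, default
3.3 ms — the timescale of a 20 ms deflection). A plain arg-min is not
used: band-limited noise superimposes dips on the flat bottom of a wide
deflection and the arg-min hops to them; the smoothed centroid is
robust, and with it the renderer→detector round trip recovers ≥95% of
8×-SNR events within ±1 ms with ≤5% spurious detections.

A 10 ms refractory (the template scale) prevents one deflection from
yielding several crossings. Within dense cascades the same channel can
fire in consecutive 4 ms frames; the refractory and template overlap
then merge some of these into one detected event. This halves the event
count of a critical session relative to ground truth — a realistic
property of threshold detection on continuous traces, shared by the
procedure the package emulates.

## Avalanche definition and the size convention

Frames are half-open intervals $[i\Delta t, (i+1)\Delta t)$ aligned to
$t = 0$, $\Delta t = 4$ ms. An avalanche is a maximal run of non-empty
frames bounded by blank frames (or the session boundary; boundary
avalanches are kept by default, `drop_boundary` removes them). Its size
is the number of active channels summed over its frames — one channel
active in two consecutive frames contributes 2 — the convention of the
avalanche literature. The occasional alternative reading, "size =
active units within a single frame", is not implemented: it describes a
per-frame occupancy, not a cascade, and is incompatible with cascades
spanning several frames.

## Fitting and acceptance

`fit_powerlaw()` is unweighted OLS of $\log_{10}$ occurrence probability
on $\log_{10}$ size, one point per distinct size with a nonzero count in
the range 1–10 (sizes with zero count are skipped by default;
`zero_policy = "fail"` makes them an error). Fitting probabilities
rather than raw counts changes only the intercept. The fit is accepted
as a power law when $R^2 \ge 0.9$. This is a descriptive straight-line
criterion, not a formal goodness-of-fit test: maximum-likelihood
exponent estimation, $x_{min}$ selection and likelihood-ratio
comparisons are deliberately out of scope, because the quantity of
interest here is the conventional straight-line slope.

`shuffle_raster()` redraws every event time uniformly over the session,
independently per event, preserving each channel's event count exactly
and respecting no refractory. This destroys all temporal structure:
binned occupancy becomes Poisson and the size distribution of a
shuffled session decays faster than any power law in its body. On
log–log axes over sizes 1–10 that curvature caps $R^2$ at roughly
0.88–0.90 for session-scale event densities (around 0.5–1 events per
frame), so the acceptance criterion cleanly separates original
(R² ≈ 0.97–0.99) from surrogate fits — the sharper the fit range and
the denser the session, the wider the separation. `shuffle_test()`
reports all surrogate fits; the median over 20 surrogates is the
summary used for the acceptance decision. ISI-preserving alternatives
were considered and not implemented: uniform redraw is the maximal
(and conventional) null of temporal independence.

## Group comparison

`compare_groups()` is the two-sided, two-sample, pooled-variance
Student's t-test on per-session $\alpha$ values
($df = n_a + n_b - 2$), with Welch's variant behind
`var_equal = FALSE`. Pairing structure is not modelled. Group summaries
report mean ± SEM (SD/√n). Sessions whose fit fails the $R^2$
acceptance are excluded from group statistics with a logged count. No
multiple-testing correction is applied by default, matching the
per-comparison convention of the analysis this package implements;
p-values for all pairwise comparisons are returned so a user can adjust
them if desired.

## The synthetic study conditions

The package's session-scale defaults, used by the acceptance script and
the end-to-end tests, are fixed once and documented here:

* 32 channels (4 × 8 grid), 4 ms generative frames, 240 s sessions;
* `seed_rate = 20`/s array-wide — at criticality this yields on the
  order of 60 000 events per session, a few nLFPs per second per
  electrode, in the range reported for in vivo multielectrode
  recordings;
* rendering at 4 kHz (the `render_config()` default is 40 kHz, the
  standard acquisition rate; 4 kHz is the analysis choice for
  simulation studies — it oversamples the 200 Hz band edge tenfold and
  keeps a 240 s, 32-channel session under 250 MB);
* 80 µV templates on 10 µV noise (8× SNR), width 20 ms;
* condition analogues are parameter presets only: "control" σ = 0.80
  versus "stimulation" σ = 0.95, six sessions each — the size of the
  effect this induces on α (≈ 0.1, with session-to-session SD ≈ 0.03)
  is comparable to the group differences the method is used to detect.

Oracle-grade runs (Borel agreement, critical slope) use sparse seeding
(1–2/s) and ≥10⁵ avalanches, as discussed above; they finish in under a
minute on one core.

## What the synthetic data do and do not show

The generator reproduces the *statistical* structure the analysis
targets — branching cascades with known size laws, realistic event
amplitudes, band-limited noise, detection at threshold — so passing
tests demonstrate that the pipeline recovers known exponents, rejects
shuffled surrogates, and detects branching-parameter shifts at the
stated sample sizes. They do not demonstrate anything about biology:
there are no oscillations, up/down states, electrode impedance
differences, movement artifacts, volume conduction or inter-channel
noise correlations, and condition labels (stimulation, anesthesia
depth, lesion) are parameter presets of the simulator, not models of
the physiology they are named after. The mapping from experimental
condition to σ is this package's construct for validation purposes.

## Numerical and degenerate-input choices

* All times are seconds, voltages µV, channel indices 0-based row-major
  over the grid; frames are 0-based.
* `borel_pmf()` is evaluated in log space; $\sigma = 0$ returns the
  degenerate unit mass at $s = 1$.
* An all-quiet session ("no avalanches") and a distribution with fewer
  than two usable sizes ("degenerate distribution") are errors with
  stage-tagged messages, not silent NAs; `shuffle_test()` reports
  per-surrogate failures in an `error` column instead of aborting the
  batch.
* Determinism: every stochastic operation takes an explicit integer
  seed; study-level seeds are derived from one master seed, and
  identical seeds reproduce recordings byte for byte.
* Truncation of runaway critical cascades at $10^4$ events biases only
  sizes ≥ $10^4$; probabilities over the fitted range renormalise by
  the avalanche count, which truncation leaves unchanged.

## Known limitations

* The straight-line $R^2$ criterion cannot distinguish a true power law
  from other heavy-tailed forms over one decade of sizes; that is a
  property of the method being implemented, and the shuffle surrogate
  is its (equally conventional) guard.
* Detection merges same-channel events closer than the refractory or
  template width, deflating sizes of dense cascades; comparisons
  between conditions processed identically are unaffected, absolute
  exponents shift slightly relative to ground truth.
* The shuffle surrogate's R² approaches 0.9 from below at moderate
  event density; very sparse sessions (few events per frame) can
  produce surrogates that still pass the straight-line criterion, so
  the surrogate test is informative only at session-scale event counts.
* The frequency-domain filter assumes the session is long relative to
  the filter's time constants (true for any realistic recording); for
  traces shorter than ~1 s the circular edge effects would matter.
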