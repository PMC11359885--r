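---
title: "Noise-elicited electrodermal activity: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-elicited electrodermal activity: models, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edanoise)
```

## The problem

Electrodermal activity (EDA) indexes sympathetic sudomotor activity and is
widely used as a marker of arousal, stress and pain. Brief environmental
noises elicit their own EDA responses, which contaminate recordings made
outside sound-controlled laboratories. This package provides a fully
simulated, testable re-creation of a graded noise-exposure experiment on
three EDA channels, the statistics used to quantify the dose–response
relation between sound level and response magnitude, and a correction that
subtracts the estimated noise-elicited component from skin conductance
scores.

Because no raw recordings are available for this design, every downstream
stage is developed and validated against the package's own synthetic-data
generator, whose generating model is exactly the model the statistics
assume. This is a strength for verification (parameter recovery can be
checked against known truth) and a limitation for external validity,
discussed at the end.

## Measurement model

The simulated instrument drives the skin with an ideal sinusoidal current
source, `i(t) = I sin(2πft + φ)` with `I = 20` μA and `f = 20` Hz, and
records the voltage across the electrodes. Treating the skin as a complex
admittance `Y(t) = G(t) + jB(t)` (conductance and susceptance, μS) in
series with a DC skin-potential source `SP(t)` (mV), the measured voltage
is

```
v(t) = SP(t) + |I / Y(t)| · sin(2πft + φ − arg Y(t))   [mV]
```

`synthesize_raw_carrier()` evaluates this quasi-statically: sudomotor
dynamics (< 0.5 Hz) are orders of magnitude slower than the carrier, so
the instantaneous-admittance approximation is accurate at the default
400 Hz sampling (20 samples per carrier cycle).

`lockin_demodulate()` recovers the components by phase-sensitive
detection: multiplying `v(t)` by reference `sin`/`cos` at the carrier
frequency, low-pass filtering the doubled products (in-phase and
quadrature amplitudes) and the raw signal itself (DC component), then
decimating. `phasor_to_admittance()` inverts `Y = I/V` on the complex
voltage phasor; the sign convention makes capacitive susceptance positive,
so noise-induced susceptance responses appear as negative deflections.

Numerical choices:

* Low-pass: Butterworth order 4, cutoff 1 Hz, applied forward-backward
  (zero phase) so demodulation does not delay response onsets. 1 Hz
  passes sudomotor dynamics while rejecting the carrier and its images.
* Zero-phase IIR filtering has edge transients at **both** ends of the
  record, so the first *and* last `settle_s` (default 5 s) are marked
  invalid, not just the initial transient.
* Output decimated to 20 Hz, ample for EDA feature extraction.
* The reference phase is assumed shared with the source (one clock); when
  it is not known, `estimate_phase_ref()` recovers it from a stationary
  calibration segment by maximizing in-phase power.

## Stimulus protocol

`build_protocol()` places one stimulus per level on a single timeline:
five 5 s stimuli at 70/75/80/85/90 dB SPL, each followed by 60 s of
relaxation, after an initial rest. The published total of 385 s is
reproduced as 60 s pre-baseline + 5 × (5 s + 60 s); the decomposition into
baseline plus stimulus/rest blocks is one consistent reading of the stated
total, adopted here as the default and overridable through the builder's
arguments.

## Generating model for synthetic cohorts

For each feature `y` (SCR amplitude, SPR amplitude, SSR amplitude, SCR
rise time, SPRET) and subject `i` at level step
`x = (dB − 70)/5 ∈ {0..4}`:

```
y_ix = (β0 + u0_i) + (β1 + u1_i)·x + ε_ix,
(u0_i, u1_i) ~ N(0, Σ),  ε_ix ~ N(0, σ²)
```

The per-5 dB fixed slopes of the default preset are +1.2 μS, −0.7 mV,
−0.2 μS, +0.4 s and +7.3% — the dose–response effects the pipeline must
recover. The remaining generator parameters are not dictated by the
design and were fixed once at values a psychophysiologist would call
realistic for this kind of cohort:

| parameter | SCR_Amp | SPR_Amp | SSR_Amp | SCR_Tris | SPRET |
|---|---|---|---|---|---|
| intercept β0 (70 dB) | 3.0 μS | −2.0 mV | −0.6 μS | 2.5 s | 12% |
| SD of u0 | 0.6 | 0.5 | 0.12 | 0.35 | 5 |
| SD of u1 | 0.3 | 0.2 | 0.06 | 0.1 | 2.5 |
| residual σ | 0.4 | 0.3 | 0.08 | 0.25 | 4 |

with intercept–slope correlation 0.2. These keep every feature several
standard deviations away from non-physical values; a hard floor
(0.05 μS / 0.4 s) guards SCR amplitude and rise time against the residual
tail and binds with probability < 1e−4, so it does not measurably bias
slope estimates.

Response timing is drawn alongside: onset latency uniform in 1.2–1.8 s
after stimulus onset, the SPR peak placed at
`SCR peak + SPRET·Tris/100`, the SSR rising over 0.8 × Tris, and the SPR
biphasic with probability 0.3 (otherwise monophasic with the amplitude's
sign).

### Trace rendering

`synthesize_traces()` renders each response as a Bateman
(difference-of-exponentials) kernel — the standard SCR waveform model —
normalized to unit peak and time-scaled so the onset-to-peak interval
equals the true rise time and the peak deflection equals the true
amplitude (base constants τ_rise = 0.75 s, τ_decay = 3 s). Biphasic SPRs
are two opposite-signed lobes with first-peak value −A/3 and second-peak
value +2A/3 relative to baseline (peak-to-peak = A, matching the
peak-to-peak amplitude definition); a small calibration loop adjusts lobe
amplitudes and onsets so the composite's extrema land on the target times
and values despite lobe overlap. Responses whose peaks fall beyond the
trace end are truncated and flagged in the annotations rather than
rejected. Rendering is linear in the true amplitudes, which the test
suite exploits as an invariant.

## Response detection and features

The detector (`detect_response()`) works per event and channel:

1. Smooth lightly (moving average, halfwidth 0.1 s).
2. Find the first sample in the post-stimulus latency window (default
   0.5–6 s) where the smoothed derivative crosses a threshold. For SC the
   direction is fixed positive; for SP/SS the crossing's sign sets the
   deflection direction, so both polarities are supported and the first
   lobe of a biphasic SPR, not the largest one, anchors the onset.
3. The threshold is `max(0.5 × channel minimum amplitude per second,
   10% of the window's peak smoothed slope)`. The relative part keeps
   slow ripple — in particular the precursor transients a zero-phase
   low-pass leaves around responses — from anchoring the onset; the
   absolute floor keeps flat traces from producing detections.
4. Refine the onset to the foot of the deflection by walking on the raw
   derivative; take the first subsequent local extremum as the peak.
5. SP only: if, after the first peak, the signal crosses beyond the onset
   level in the opposite direction by at least 25% of the first
   deflection, the response is biphasic and the opposite extremum is the
   second peak. A monophasic decay returns toward baseline without
   crossing it, so plateaus and tails cannot masquerade as second lobes.

Features follow directly: amplitudes are onset-to-peak differences
(peak-to-peak for biphasic SPRs, so a +0.5/−1.0 mV lobe pair gives
−1.5 mV), rise time is SCR peak minus onset time, and SPRET is
`100·(t_SPR,peak − t_SCR,peak)/Tris`. For biphasic SPRs the **second**
peak anchors SPRET: the amplitude definition is peak-to-peak and the
second peak is the response's extremum. Events with no qualifying
deflection (below the 0.02 μS / 0.05 mV / 0.01 μS channel thresholds)
yield missing features — never zeros — and missingness propagates to the
statistics (complete cases within the ANOVA, all available observations
in the mixed model).

On clean rendered traces the detector recovers onset and peak times
within one sample (20 Hz) and amplitudes within well under 5%; through
the full carrier/demodulation path, finite filter bandwidth adds a small
positive bias to rise times and attenuates sharp SPR lobes, which is why
the end-to-end recovery check targets the SCR amplitude slope.

## Statistics

`rm_anova()` computes the one-way within-subject decomposition
(SS_total = SS_subjects + SS_treatment + SS_error) and tests
`F = MS_treatment / MS_error` on `(k−1, (n−1)(k−1))` degrees of freedom.
No sphericity correction is applied. Pairwise level contrasts are paired
t tests with the Sidak adjustment `p_adj = 1 − (1 − p)^m` over all
`m = k(k−1)/2` comparisons (10 for five levels); zero-variance difference
vectors give p = 0 when means differ and 1 otherwise.

`fit_lmm()` fits the random-intercept/random-slope model by REML via
`lme4::lmer`, reporting the fixed slope per 5 dB with a Wald 95% interval
and Wald z p-value. Coding `x` in raw dB instead of 5 dB steps rescales
the slope by exactly 1/5 (an invariant in the test suite). Exactly
collinear (noise-free) input defeats a REML optimizer, so that degenerate
case is detected up front (per-subject OLS residuals ≈ 0) and solved
exactly by per-subject OLS with zero variance components; genuine
non-convergence raises a warning and is flagged in the result, never
silently replaced.

## Correction for noise-elicited EDA

Measured EDA is modeled as intrinsic plus noise-elicited activity.
`fit_amplitude_vs_level()` fits the mean SCR amplitude per level as either
`a + b·x` or `a·e^(b·x)` (x in 5 dB steps; the exponential is fitted by
nonlinear least squares initialized from the log-linear fit, falling back
to linear with a warning when means are non-positive). Both forms are
provided because the amplitude–level relation is plausibly but not
certainly exponential; the exponential is the package default for the
pipeline. `attribute_responses()` links responses to events whose latency
window (default 0.5–6 s) contains the response onset, nearest preceding
event winning and ties going to the earlier event. `correct_bins()` then
subtracts, within each time bin (default 300 s), the model-predicted
amplitudes of attributed responses from the summed SCR amplitudes.
Corrected scores are deliberately not clipped at zero: negative bins are
informative — they indicate the model overcorrects there. The model is
fitted at population level; per-subject refits are possible by passing a
subject's rows, but individual-level learning is outside the present
scope.

## Problem sizes and verification

The test suite and the acceptance script run entirely on generated data
at the study's scale where that is what is being verified, and smaller
where it is not: slope recovery uses 20 replicate cohorts of 40 subjects
(feature level) and 4 replicates of 10 subjects through the full
carrier/demodulation path at 400 Hz; Wald interval coverage uses 100
replicate cohorts; detector ground-truth agreement uses 6 subjects × 5
events. These sizes give Monte-Carlo error comfortably inside the
tolerances being asserted.

## What the generator does and does not emulate

Emulated: the dose–response structure (fixed effects per 5 dB with
correlated subject-level intercepts and slopes), physiologic response
geometry (Bateman kernels, monophasic/biphasic SPs, channel-consistent
timing), tonic baselines, optional slow drift, and the full AC-carrier
measurement chain.

Not emulated: electrode polarization and motion artifacts, habituation
across repeated stimuli (stimulus order effects), overlapping responses
from closely spaced events, noise-type-specific effects beyond level
(the one-type-per-level design confounds them, so they are not
identifiable and not simulated), and measurement noise on the carrier
itself. Passing round-trip and recovery tests therefore demonstrates the
pipeline's internal correctness under the stated model, not performance
on field recordings; with real data the detector thresholds and latency
window are the parameters most likely to need tuning.

## Known limitations

* The pre-baseline duration is inferred from the total recording length,
  not stated independently.
* SPRET through the carrier path inherits bias from rise-time smearing at
  the demodulator's bandwidth; feature-level analyses are unaffected.
* The ANOVA treats level as a five-category factor on raw feature values;
  no transformation or sphericity correction is applied.
* The correction assumes additivity of intrinsic and noise-elicited
  amplitudes and a stable amplitude–level law across time.
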