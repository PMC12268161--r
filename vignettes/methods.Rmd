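---
title: "Beta burst-driven adaptive DBS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta burst-driven adaptive DBS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(burstloop)
```

## The control problem

Prolonged beta-band (13–30 Hz) bursts in the subthalamic nucleus (STN) are
associated with gait impairment and freezing of gait in Parkinson's disease,
and their durations shorten under deep brain stimulation. `burstloop`
implements the full closed-loop stack built around that observation:

1. a streaming detector that turns an STN LFP channel into the *duration of
   the current beta burst*;
2. a single-threshold control policy: stimulation amplitude is incremented
   when the current burst duration exceeds a participant-specific duration
   threshold and decremented otherwise, in discrete 0.1 mA steps,
   ramp-limited (0.1 mA/s up, 0.05 mA/s down — down is half of up to bias
   stimulation upward) and clamped to a therapeutic window
   `[I_min, I_max]` that never exceeds 125% of the clinical amplitude;
3. the calibration pipeline that selects the beta band, the two thresholds
   and the window from stimulation titrations;
4. the behavioural read-outs used to evaluate such a controller: percent
   time freezing, swing-time asymmetry, stride-time arrhythmicity, mean peak
   shank angular velocity and wrist RMS velocity;
5. ground-truth-labelled synthetic generators, including a
   stimulation-dependent LFP plant, so every stage can be exercised and
   validated closed-loop without patient recordings.

## Envelope and burst extraction

The detector mirrors a device-style pipeline. The streamed LFP (500 Hz
nominal) is band-passed with a 128-order FIR filter over a 6 Hz band centred
on the participant's beta peak. The FIR design is windowed-sinc (Hamming), the
classical deterministic choice when only order and band are given; the design
normalises passband gain to unity at the band centre, so a centre-frequency
sinusoid of amplitude $A$ yields an envelope of $A^2$. The filtered signal is
squared; local maxima of the squared signal are linearly interpolated to form
the envelope (before the first and after the last maximum the nearest maximum
value is held). Numerical conventions:

* **Peaks** are strict local maxima; a flat plateau contributes its last
  sample. Endpoints never qualify, which is what makes streaming and offline
  peak sets identical.
* **Group delay.** The linear-phase FIR delays by `order/2` samples; both the
  offline and the streaming paths compensate by flushing `order/2` zeros, so
  burst timestamps align with the input clock and the two paths agree
  exactly, sample for sample, for any chunking of the stream.
* **Bursts** are maximal runs of envelope samples strictly above the power
  threshold, reported at sample resolution (2 ms at 500 Hz); sub-sample
  interpolation would be spurious given the envelope is itself interpolated.
  A run touching the end of the buffer is flagged *ongoing*.
* **The power threshold** is the mean of the local minima (troughs) of the
  45–65 Hz envelope of an OFF-stimulation recording, computed through the
  same FIR/square/interpolate pipeline (centre 55 Hz, width 20 Hz, same
  order). The troughs of this high-frequency envelope track the aperiodic
  floor, so beta excursions above it mark genuine bursts.
* **The current burst duration** — the controller's input — is the elapsed
  time of the ongoing burst when the envelope is above threshold, otherwise
  the duration of the most recently completed burst, 0 if none has been
  seen, capped at the 5 s buffer capacity (which covers plausible duration
  thresholds with a wide margin).
* **Blanking.** After every executed stimulation step the detector blanks
  0.5 s of envelope (configurable): blanked samples neither extend nor
  terminate bursts. A burst ongoing at blank start is held; the first
  post-blank sample decides whether it bridges the blank or ended at the
  blank start. The stimulation-change artifact in real recordings motivates
  both this and the slow ramp; no artifact-removal is attempted.

## Controller semantics

Decisions are taken once per second per hemisphere (the cadence that lets
every up-decision execute at 0.1 mA steps and 0.1 mA/s). Ties at the duration
threshold decrement, because only strictly longer bursts count as
pathological. Ramp limiting is a per-direction minimum dwell: a step in
direction $d$ executes only if `step / rate(d)` seconds have passed since the
last executed step — 1 s after an up step, 2 s before a down step. The dwell
is keyed to the direction of the *candidate* step: a down decision therefore
never delays a later up decision beyond the up dwell, preserving the
bias-stimulation-up intent of the asymmetric ramp. Runs start at `I_min`
(conservative, inside the window, consistent with the upward bias).
Hemispheres are fully independent; a hemisphere without usable sensing is
held at 100% clinical amplitude.

The *initial* duration threshold from calibration is the mean OFF burst
duration. On a plant whose bursts shorten with any stimulation, that value
sits above everything the controller will observe ON stimulation, so it
drives amplitude to the window floor — which is why, clinically, thresholds
are adjusted after calibration against the observed modulation. In-silico
runs that exercise active adaptation therefore set the duration threshold to
the plant's mean duration at a target amplitude inside the window; the
demonstrations in the test suite use a plant with mean duration
$1.1 - 0.3 I$ seconds and a 0.35 s threshold, placing the crossing at
2.5 mA in a 1.5–3.5 mA window. The steep modulation (0.3 s/mA) makes the
stochastic equilibrium of the bang-bang controller sharp; with shallow
modulation the equilibrium amplitude becomes diffuse, which is a property of
the control law, not of the implementation.

## Energy-matched control conditions

Continuous DBS (`hold_continuous`) holds 100% clinical amplitude. Total
electrical energy delivered (TEED) is compared across conditions through the
unit-impedance proxy $\sum I^2 f \cdot pw \cdot dt$ (140.1 Hz, 60 µs, mA);
only ratios are meaningful.

Randomly adapting DBS (rDBS) must vary with the same ramp, window and dwell
statistics as the recorded aDBS run while delivering the same energy, but
with no link to the biomarker. Permuting the executed *steps* of a run
cannot achieve this: reordering the increments of a trajectory reorders its
partial sums and changes the time spent at each amplitude, so the energy of
a step-shuffled replay is essentially unconstrained. `generate_rdbs`
therefore shuffles contiguous *blocks* of the recorded amplitude trace. The
trace is cut at upward crossings of its median level (so block boundaries
sit at nearly equal amplitudes), blocks of roughly 50 s are uniformly
permuted, and the shuffled trace is replayed as a rate-limited pursuit: one
0.1 mA step per allowed per-direction dwell, clamped to the window. The
brief catch-up ramps at block boundaries are the only energy mismatch; with
median-crossing boundaries they are one or two steps and the mismatch is a
fraction of a percent. An unshuffled (identity) replay reproduces the source
trace exactly.

## Calibration

`calibrate_hemisphere` reproduces the parameter-selection pipeline on a set
of titration runs (OFF plus several amplitudes up to 125% of clinical):

* Welch PSDs (1 s Hann window, 50% overlap) per level.
* Candidate beta peaks: local PSD maxima in 13–30 Hz rising at least 3 dB
  above a log–log linear aperiodic fit over 5–45 Hz excluding 13–30 Hz. The
  prominence criterion is a package choice; spectra show the peaks but no
  published cut-off exists.
* Among candidates, the 6 Hz band whose mean burst duration falls fastest
  with amplitude (most negative ordinary-least-squares slope, amplitude in
  mA because the device steps in mA) is selected. A hemisphere with no
  qualifying peak is flagged unusable ("insufficient modulation").
* The initial duration threshold is the mean completed burst duration of the
  OFF (or `I_min`) run, requiring at least 10 bursts.
* The therapeutic window: `I_min` is the lowest amplitude whose behaviour
  satisfies the benefit rule — by default percent time freezing at most half
  the OFF value, or at least 50 points below it (the absolute branch handles
  OFF values near 100) — and `I_max` the highest amplitude with no
  side-effect flag at or below it, behaviour within 10 points of the best
  level, capped at 125% of clinical. "Acceptable benefit" is clinician
  judgement in practice, so both rules are explicit, configurable
  predicates. A tremor-dominant floor can be imposed via `i_min_floor_ma`;
  it is an input, not something the package infers.

## Gait and bradykinesia metrics

Stepping-in-place forces (1000 Hz, dual plates) are normalised to percent
body weight (measured weight, or the mean total force when not supplied).
Gait cycles: foot-off and foot-strike are crossings of a 20% BW unload
threshold with a 50 ms dwell on both sides (debounce); swing is off→strike,
stride is strike→strike of the same foot. Asymmetry is
$100\,|\ln(\overline{sw}_{short}/\overline{sw}_{long})|$ and arrhythmicity
the mean over legs of the stride-time coefficient of variation, with the
sample (n−1) standard deviation — the usual convention at small stride
counts. Freezing: during effective stepping each foot periodically drops
below 15% BW while the contralateral plate exceeds 85% BW; spans of at
least 1 s without any such excursion are freezes (below one stride period
the absence of an excursion is indistinguishable from a slow step), merged
across gaps shorter than 0.2 s. The 20% segmentation threshold is kept
distinct from the 15% excursion bound to avoid chatter; all are
configurable. Metrics on (essentially) fully frozen trials are reported as
undefined rather than numbers.

Shank gyroscopes (128 Hz) are low-passed with a zero-phase 8th-order
Butterworth at 9 Hz — "zero-phase order n" is read as designing order n and
running it forward–backward, with reflect padding of three filter orders to
suppress edge transients — and the sagittal component is the first principal
axis of the 3×3 covariance, sign-fixed so swing peaks are positive
(positive skewness); the output is rotation-invariant up to sign and flagged
low-confidence when the first component explains less than half the
variance. Mid-swing is the maximum of each region where the velocity exceeds
0.4× the 95th percentile of its positive values (scale-free across slow and
fast walkers); swings are bounded by the surrounding zero crossings; the
swing angular range is the time integral of angular velocity over the swing
(an angle, in degrees — the range-of-velocity reading would not be an
angle), and stride time the interval between successive same-leg mid-swings.

The logistic freezing model scores every step using arrhythmicity and
asymmetry over the last six steps — steps pooled across legs and ordered by
mid-swing time; a window that cannot support a metric carries the previous
value forward — plus the stride time and swing angular range of the last
step, each standardised by the model's stored scaling. Steps with
probability above 0.7 form freeze intervals (swing start of the first to
swing end of the last). Evaluation is per step, the natural grid for
stride-level features. The published model's coefficients are not
distributed, so the model is a configurable parameter plus
`fit_freeze_model`, a maximum-likelihood logistic fit with a 30% held-out
AUROC report; the packaged default is fitted on the labelled synthetic
corpus (`synth_freeze_corpus`), which is cleanly separable — the fit
saturates, which is expected and only the ranking matters for detection.

Wrist flexion-extension angular velocity is low-passed (zero-phase 4th-order
Butterworth, 4 Hz) before computing the RMS velocity and the rate of
positive-going zero crossings of the demeaned signal (demeaning gives gyro
drift immunity).

## The synthetic generators

The generators define the study conditions for every recovery test; their
defaults are fixed, not tuned per test.

**LFP plant.** A gated-oscillator model rather than an autoregressive one,
so burst truth is exact: a beta sinusoid (default 15 Hz) switched by bursts
with exponential inter-onset gaps (1 burst/s, 0.1 s refractory gap) and
50 ms raised-cosine edges; durations are Gamma (shape 3) with mean
`max(0.1, d0 − k·I)` — 0.4 s OFF by default, shortening 0.08 s/mA — using
the amplitude in force when the burst starts (a mid-burst amplitude change
lets the running burst complete). The background is Gaussian 1/f (exponent
1) produced by a cascade of one-pole/one-zero sections with poles log-spaced
at 3 per decade and zeros a factor $10^{\alpha/6}$ above — the classical
shelf-cascade approximation — normalised to unit output variance and scaled
to `bg_sd = 0.25`. Added 45–65 Hz noise (`gamma_sd = 1.2` broadband through
the 128-order FIR) sets the trough threshold near 0.07 envelope units for
the default background; with unit burst amplitude the default burst SNR
(plateau over threshold) is therefore about 14, and detection-side recovery
of planted mean durations is accurate to within a few percent (about −11%
at SNR 3, inside the 15% recovery band the tests assert). Every stimulation
step injects an additive exponential artifact (peak 10× burst amplitude,
τ = 100 ms) — the slow ramp plus blanking is what makes the detector immune
to it. All randomness flows through private RNG substreams whose
consumption is per-sample deterministic, so `plant_step` output is
bit-identical for any chunking of the same amplitude schedule — the property
the streaming-equivalence tests rest on.

**Force plates.** Strides are built as double support → unload ramp → swing
→ reload ramp with raised-cosine transfers (0.12 s); the full-unload dwell
is shortened by the exact time the ramps spend below 20% BW, so the planted
swing times are what the 20% criterion recovers. An integer number of
jittered strides is rescaled to fill each stepping segment exactly, so no
quiet residue borders a freeze episode. Freezes replace alternation with
5 Hz trembling inside 30–70% BW (or static 50/50), in episodes of roughly
8 s separated by at least 2.5 s of stepping.

**Shank IMUs.** Raised-cosine sagittal velocity pulses (1.1 s stride,
0.4 s swing, 300 deg/s peak; legs half a stride apart) embedded in a random
3-D rotation with gyroscope noise; freeze episodes are short, shallow,
irregular shuffling steps (0.55 s stride, 130 deg/s peak — strong enough to
clear the stride-segmentation criterion, as festinating steps must be to be
scored at all). **Wrist** trials are a sinusoid plus noise with closed-form
truth.

What the generators deliberately do not emulate: non-sinusoidal beta
waveform shape, cross-hemisphere coupling, tremor oscillations,
medication-state drift, force-plate cross-talk, soft-tissue IMU artifacts,
or any correlation structure between neural and behavioural noise beyond
the explicit linkage below. Passing recovery tests therefore demonstrates
correctness of the algorithms under the stated signal model, not clinical
performance.

**Neural–behaviour linkage.** `run_experiment` couples the plant to the
behavioural generators through a logistic map from mean detected burst
duration to a 0–1 impairment level (midpoint 0.3 s, width 0.05 s, gain
0.85) that scales planted freeze fraction, gait variability, asymmetry and
wrist slowing. This is an explicit simulation device — worse bursts, worse
behaviour — not a claim about patients; gain 0 decouples behaviour entirely
and is used as the null control in the tests. Within a replicate all
conditions share the behavioural seed, so condition contrasts are paired.

## Problem sizes

The validation suite uses the sizes at which its guarantees are stated:
streaming-vs-brute-force equivalence on 100 random envelopes with random
chunkings; twenty 600 s closed-loop runs for the controller invariants and
the equilibrium-tracking check; 50 shuffles of a 600 s adaptation pattern
for energy matching; 90 s titration recordings for calibration recovery
(at 60 s the OFF burst-duration estimate is within sampling noise of the
10% recovery band, so calibration recordings are kept at 90 s); 100 s
stepping trials across planted freeze fractions 0–90%; and a three-trial
synthetic IMU corpus for the freezing model. `scripts/acceptance.R` re-runs
the same pipeline end-to-end from a single seed.

## Known limitations

* The controller equilibrium tracks the threshold-crossing amplitude only
  when burst-duration modulation is steep relative to the duration
  dispersion; the package reports, but cannot sharpen, a diffuse
  equilibrium.
* The streaming detector finalises bursts only up to the last envelope peak
  (beta-period latency) plus the FIR group delay (128 ms at 500 Hz); the
  control decision lags the physiology accordingly, as it does on the
  device architecture it mirrors.
* The freeze-probability model ships without published coefficients; results
  depend on the corpus it is fitted to, and the packaged synthetic default
  is far easier than clinical data.
* Blanking excludes artifact samples but no artifact subtraction is
  attempted; heavily artifactual hemispheres should be flagged unusable at
  calibration, as the pipeline does.
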