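---
title: "Methods: wearable sleep staging from PPG and accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable sleep staging from PPG and accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Gold-standard sleep staging assigns each 30-s epoch of a night to Wake, REM
or one of the non-REM stages from EEG/EOG/EMG. A wrist wearable sees none of
those signals, but it does see two stage-dependent surrogates: cardiac
interbeat intervals from a reflective PPG sensor, and gross body movement
from a triaxial accelerometer. Heart rate falls and respiratory sinus
arrhythmia strengthens in deep non-REM sleep; low-frequency rate
oscillations and movements mark wake and REM. `wearstage` classifies each
epoch into the merged 4-class vocabulary Wake / N1–N2 / N3 / REM (N1 and N2,
or S1 and S2 under R&K scoring, are pooled; S3 and S4 pool into N3) from
exactly two inputs:

* an instantaneous heart rate (IHR) series: pulse troughs are detected in
  the band-passed PPG, beats falling in seconds where the acceleration
  magnitude deviates from 1 g by more than 0.1 g are discarded, the
  surviving interbeat intervals (plausibility band 0.27–2.0 s, i.e. roughly
  30–220 bpm) are linearly interpolated onto a 10 Hz grid and inverted to
  bpm. Samples without valid data — invalid gaps, non-rest epochs, regions
  before the first or after the last valid beat — carry a 0 sentinel rather
  than an imputed value, so "no data" is an explicit input state.
* per-epoch activity counts: each axis is low-pass filtered (3rd-order
  Butterworth, 1 Hz), a per-second gravity estimate (the mean absolute
  value of the filtered axis within the second) is subtracted per sample
  with negative residuals clamped at zero, and the 1-s sums are added over
  each 30-s epoch. Counts are computed for the whole recording and are
  **not** zeroed outside rest — the classifier itself uses high counts as
  evidence of Wake.

The classifier is a two-part network. A stack of residual blocks — dilated
1-D convolutions (kernel 5) with SELU activations, the block input
concatenated to the conv output, then kernel-1 dense layers — interleaved
with max-pooling (factors 5, 5, 4, 3) reduces the 10 Hz IHR to one
64-dimensional feature vector per epoch. Concatenation (rather than
addition) of skips preserves SELU's self-normalising statistics. The
per-epoch activity count joins the feature vector after the extractor: with
a 10 Hz input and a 1/30 Hz activity series, the epoch grid is the only
junction where both exist without resampling. Three stacked bidirectional
GRUs (64 units per direction), with the stack input concatenated to its
output, give every epoch the context of the whole night; a dense layer with
softmax yields the 4-class posterior. Epochs outside the main resting
period are forced to Wake in the output hypnogram; the posterior itself is
left untouched.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| motion gate | 0.1 | g | PPG is unusable during gross motion; beats in seconds above the gate are discarded |
| rest threshold | 0.30 | likelihood | epochs below it are excluded from staging (inputs zeroed) |
| IBI band | 0.27–2.0 | s | ~30–220 bpm; longer bridges (missed beats) are never interpolated |
| IHR rate | 10 | Hz | fixed input rate of the conv stack; 300 samples per epoch |
| pooling | 5·5·4·3 = 300 | – | must take 10 Hz to exactly one feature per 30 s |
| receptive field | ≈ 8.1 | min | matched to the longest rolling window (8.5 min) used by classic HRV-feature stagers; the build rejects configurations outside 5–12 min |
| dilation schedules | (1,2,4) ×4 blocks, (1) last | – | a uniform (1,2,4) in all five blocks would give a ~20 min receptive field, far past the design band, so the last block keeps a single undilated conv |
| input scalings | IHR/60, log1p(act)/log1p(1000) | – | frozen affine maps; per-recording normalisation would destroy the 0-sentinel semantics |
| optimizer | Adam, lr 1e-3 (2e-3 in the bundled experiment) | – | whole recordings as batch elements, padding masked |
| early stopping | patience on validation κ | – | model selection aligned with the headline agreement metric, not the loss |

Where the underlying procedure came from published work whose internals are
not public (the PPG pre-filter, the QRS detector and localizer, the exact
1-s motion features of the rest segmenter), the package substitutes a
documented standard construction: a 0.4–8 Hz zero-phase band-pass with
trough prominence gating and parabolic sub-sample refinement for pulses; a
band-pass → derivative → square → integrate → adaptive-threshold detector
with a 250 ms refractory and ±50 ms raw-signal localization for QRS; zero
crossings, windowed autocorrelation periodicity/cadence, and gravity-axis
projection for the motion features. These are substitutes, not claimed
re-implementations.

## Clock synchronization

The wearable clock is modelled as `wearable = psg · (1 + drift) + offset`
(the one direction convention used everywhere). Both IBI series are cleaned
with a running-median ectopic filter (a single missed beat creates a
double-length interval that is otherwise still inside the plausibility
band), resampled to 4 Hz, and the (offset, drift) grid — ±120 s in 0.25 s
steps, ±2×10⁻⁴ in 10⁻⁵ steps — is searched with FFT cross-correlations.
Because a drift error can be compensated at the overlap centre `tau_c` by an
offset shift, the correlation surface has a ridge
`offset ≈ offset* + tau_c (drift* − drift)`; the refinement therefore
profiles drift along that ridge with exact Pearson correlations before a
final local polish at 10× finer steps. Synchronization fails (a typed
condition carrying the best candidate) when the overlap is under 10 min or
the best correlation is below 0.5. Near the optimum the surface is tied at
double precision, so the reported argmax is meaningful only to the
refinement grid (0.025 s, 10⁻⁶).

## The synthetic-night generator

The simulator emulates exactly the structure the classifier assumes:

* a first-order Markov hypnogram whose transition matrix is
  `0.88 I + 0.12 · 1 πᵀ`, so its stationary distribution is exactly the
  pooled stage-prevalence vector π = (17.7, 50.6, 16.8, 15.0)%/1.001 and
  epoch-to-epoch persistence is ~0.9 (bouts of ~4 min); walking margins
  before (30 min) and after (10 min) the in-bed period are forced Wake and
  excluded from lights-off;
* beats by integral pulse frequency modulation: a beat whenever the
  integral of `r(t)/60` crosses an integer, with `r(t)` = stage mean (70 /
  62 / 58 / 66 bpm for Wake / N1–N2 / N3 / REM) + RSA sine (0.25 Hz,
  strongest in N3) + low-frequency sine (0.095 Hz, strongest in Wake and
  REM) + white jitter, clamped to 30–180 bpm;
* a PPG rendered as one identical fixed-width pulse template per beat — a
  locally symmetric trough exactly at the beat instant with a fast rise to
  a systolic bump — plus baseline wander and sensor noise; during movement
  bursts the waveform is **replaced** by high-amplitude noise, so pulse
  detection must fail there and the 0.1 g gate is genuinely exercised. A
  fixed template is deliberate: a phase-warped periodic waveform gives the
  trough an interval-dependent shape whose filtered localization bias
  masquerades as clock drift;
* an accelerometer with a piecewise-constant unit gravity vector (posture
  changes), stage-dependent Poisson movement bursts (Wake ≫ REM > N1–N2 >
  N3) containing a gravity-aligned component so the magnitude deviation
  reliably reflects the burst, rhythmic ~2 Hz walking in the active
  margins, and sensor noise;
* a wearable clock applied to the wrist channels sample-by-sample, with
  ground truth (true beats on both clocks, true rest mask, true clock
  model) stored alongside.

The stage-conditional autonomic numbers are configuration chosen to make
stages separable, not estimates of any cohort: no public quantitative
description of stage-conditional HRV was available to calibrate against.
What a passing end-to-end test shows is therefore that the pipeline can
learn and recover stage structure of the kind it assumes — not that it
reaches any particular agreement on real wrist recordings, which carry
artifact types (arrhythmia, perfusion loss, non-wear) the generator does
not model, and which the simulator's Markov hypnogram (no explicit sleep
cycles) also simplifies.

## Numerical choices and degenerate inputs

* All forward–backward filtering goes through an odd-reflection, DC-exact
  padding wrapper: `signal::filtfilt` pads with zeros, which would give a
  constant input a startup transient (and gravity-only accelerometer data
  non-zero counts).
* The activity-count recipe is only approximately orientation-invariant:
  the per-axis absolute-deviation sum depends on the L1 norm of the burst
  direction, so exact invariance under large rotations is impossible; for
  modest wear-angle changes (~10–15°) with per-axis gravity components
  exceeding the burst amplitude the change stays below 5%.
* The rest discriminant regularises its pooled covariance with
  `1e-4 · mean(diag) · I`, so constant synthetic features cannot make it
  singular. The shipped discriminant (`rest_lda_synthetic.json`) is trained
  on simulator-labelled nights and is labelled synthetic — no clinically
  trained weights are distributed.
* Masked padding of batch recordings is *asymptotically* invariant, not
  exactly: the conv halo spills about half a receptive field into the
  padding and the forward GRU state decays geometrically through it. Once
  padding exceeds the halo the loss is stable to <1e-4.
* Zero-initialising the output layer makes the initial posterior exactly
  uniform (initial cross-entropy = ln 4) and the chance-level behaviour of
  untrained models exact.
* Signed-rank equivalence CI: zero differences are dropped, ties are
  handled by the Walsh-average construction, exact null quantiles are used
  up to n = 25 and the normal approximation beyond; the Hodges–Lehmann
  estimate is the Walsh-average median. The "equivalent" verdict is
  `[CI_low, CI_high] ⊆ [−δ, δ]`; δ is always caller-supplied, since any
  published margin is specific to the comparison it came from.
* Quartiles use linear interpolation between order statistics (R type 7);
  degenerate-variance samples report the median form directly since the
  normality test is undefined for them.
* Per-class agreement on pooled counts is one-vs-rest binary κ — the
  reading under which the published per-class values (0.73 / 0.55 / 0.63 /
  0.72) reproduce exactly from the published cells. (The printed total of
  that table, N = 393,012, differs from the sum of its printed cells,
  393,224; all derived values match the cells.)

## Problem sizes used by the bundled experiment

`synthetic_experiment()` trains a reduced-width model (channels 6–24, GRU
24/direction — the full-width default is channels 16–64 with GRU 64) on 40
simulated 8-h nights and evaluates pooled agreement on 10 held-out nights,
with Adam at lr 2e-3 (global gradient norm clipped at 5), batches of 2
recordings, at most 12 passes with early stopping on validation κ
(patience 6, not before pass 8 — the loss sits on a majority-class plateau
for several passes before N3 and REM emerge), plus a 10-night
shuffled-label control trained for 4 passes. These sizes are the package's standard benchmark
configuration; wider models and more nights train the same way through
`stager_config()` and `train_config()`.

## Known limitations

* The simulator does not model PPG morphology (dicrotic notch), apnea or
  arrhythmia, naps/multi-rest nights, or multi-night subjects; the rest
  segmentation assumes a single main resting period.
* The published architecture leaves layer counts and kernel sizes open; the
  defaults here are one self-consistent instantiation (receptive field
  anchored at ~8 min), not a weight-for-weight reproduction, and the MAC
  accounting consequently describes *this* network.
* Training is CPU-bound single-threaded R/C++; it is meant for experiments
  at the bundled scale, not for large clinical corpora.
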