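---
title: "Simulating and scoring lateralized readiness potentials"
author: "lrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring lateralized readiness potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrpipe)
```

## The measurement problem

The lateralized readiness potential (LRP) indexes response preparation in
primary motor cortex. In a two-choice task, activity over the motor strip
contralateral to the responding hand becomes more negative than ipsilateral
activity shortly before a button press. Because the lateralization is small
(a few microvolts) relative to background EEG, the LRP is derived from
averaged epochs at electrodes C3 and C4 using the Coles double subtraction

\[
\mathrm{LRP}(t) = \tfrac{1}{2}\left[ (C4 - C3)_{\text{left hand}}(t) +
(C3 - C4)_{\text{right hand}}(t) \right],
\]

which cancels activity that is not lateralized with respect to the
responding hand. Motor preparation appears as a negative deflection;
`lrpipe` stores amplitudes signed in microvolts and makes no plotting-order
assumption.

Two locked variants are analyzed: stimulus-locked (S-LRP, preparation) and
response-locked (R-LRP, execution). `lrpipe` implements the full chain —
trial scheduling, stimulus construction, synthetic EEG, preprocessing,
epoching and rejection, LRP derivation, onset/amplitude scoring, and group
statistics — so that every stage can be validated against known ground
truth, which matters because real EEG for this design is not generally
redistributable.

## Trial schedules

`build_schedule()` reproduces a blocked cued-response design: by default 4
blocks x 10 trials, each trial a 65 s audio track (5 s lead-in, then 40
cued button presses separated by ISIs drawn evenly from 1100--1400 ms with
no immediate repetition). Four listening conditions (high-groove music,
low-groove music, spectrally matched noise, silence) are ordered so that no
two consecutive trials share a condition and no condition occurs more than
three times per block; hands are balanced within every trial. The defaults
give 1600 cued responses (800 per hand; 400 per condition, 200 per hand and
condition) and block/total durations of 11.58 and 46.33 minutes:

```{r schedule}
sched <- build_schedule(seed = 1)
sched
response_counts(sched)$per_condition_hand
```

Sequences are generated by constraint-aware sequential sampling with
bounded restarts; infeasible parameter combinations fail with an error
rather than silently relaxing a constraint.

## The synthetic-EEG generator

`simulate_recording()` renders a continuous multichannel recording on a
reduced nine-channel montage (C3, C4, Cz, Fp1, Fp2, the two mastoids, and
vertical/horizontal EOG) — the channels the analysis actually consumes; a
full research montage adds nothing to the validation and multiplies cost.
The default sampling rate is 256 Hz (1024 Hz available via the `srate`
argument); recovery tolerances are expressed in samples so the choice is
explicit.

Per correct response, a raised-cosine template (default: onset 180 ms after
the cue, 120 ms rise to a -2.5 uV peak, 200 ms decay) is added to the
electrode contralateral to the pressed hand. The template is locked to the
*stimulus*, matching the stimulus-locked scoring used for parameter
recovery. A useful property of the raised cosine is that its 50%-of-peak
point falls exactly at half the rise time, giving an analytic ground truth
(onset + rise/2 = 240 ms by default) for the onset scorer.

Reaction times follow an ex-Gaussian (mu 350 ms, sigma 50 ms, tau 100 ms),
the standard descriptive RT model; errors flip the pressed hand with a
configurable rate (default 5%). Blinks occur as a Poisson process (default
15/min) with biphasic 100--400 ms waveforms of 100--200 uV on VEOG,
propagated to other channels with fixed attenuation factors. Background
noise is white Gaussian per channel (default 1 uV).

What the generator does *not* emulate: 1/f spectral structure, alpha
rhythms, slow drifts, electrode pops, muscle artifact, or overlapping
component families (no auditory evoked potentials, no entrainment). Passing
recovery tests therefore certify the *estimators* under controlled
conditions — unbiasedness of the scoring chain, correct lateralization
bookkeeping, calibrated statistics — not robustness to every pathology of
real scalp data.

## Stimulus construction

`average_tracks()`, `spectral_envelope()` and `synthesize_matched_noise()`
implement spectrally matched noise: the magnitude spectrum of a grand
average of songs is turned into a smoothed upper envelope (moving maximum
followed by a moving-average low-pass; window width 50 Hz by default —
the envelope estimator's parameters are artifact choices, surfaced in the
arguments, because no canonical values exist), then imposed on the
magnitudes of white Gaussian noise, leaving the phases random, and
inverse-transformed. Each channel is scaled to its own maximum amplitude.

`embed_intensity_changes()` implements the auditory response cues of an
active-listening variant: 20 increasing and 20 decreasing intensity events
(default +/-15 dB, 300 ms duration, 30 ms linear-in-dB ramps) at ISIs drawn
evenly from 1000--1300 ms. The plateau gain is exactly `10^(depth/20)`,
which the tests verify against the closed form to 1%.

## Preprocessing

The conditioning chain is deliberately plain and linear: mastoid-average
re-referencing; a zero-phase Butterworth band-pass (defaults 0.05--100 Hz)
realized as order-2 high-pass and low-pass sections applied forward and
backward; inverse-squared-distance interpolation for bad channels (refused
for C3/C4, which carry the signal of interest); and least-squares EOG
regression estimated on blink-rich segments as the deterministic ocular
correction. An ICA-based correction requires a component-selection judgment
that is neither deterministic nor testable against ground truth, and the
only consumers of the cleaned data here are C3/C4; regression with known
propagation coefficients is exactly recoverable in simulation, which is
what the tests exercise.

Two filtering conventions deserve note. First, the half-amplitude (-6 dB)
cutoff convention falls out of the design: each order-2 section is -3 dB at
its design frequency, and the forward-backward application squares the
magnitude response, so the stated cutoffs are exactly half-amplitude.
Second, each pass removes the signal mean before filtering and restores it
scaled by the squared DC gain; this keeps constants exact under a low-pass,
annihilates them exactly under a high-pass, and avoids step transients at
the recording edges. High-pass and low-pass run as a cascade rather than a
single band-pass design for numerical stability at the 0.05 Hz corner.
Zero-phase application is itself a choice the filtering literature leaves
open for ERP work; it is used here because onset latency is a headline
measure and phase delay would bias it.

## Epoching, rejection, averaging

Epochs are 1000 ms: stimulus-locked -200..+800 ms with a -200..0 ms
baseline, response-locked -800..+200 ms with a -800..-600 ms baseline; each
window starts at its baseline start, the minimal placement consistent with
both the stated epoch length and the stated baselines. Rejection applies,
in strict precedence: incorrect response; response during stimulus
presentation (RT below the cue duration, 200 ms visual / 300 ms intensity
change); RT strictly greater than 1200 ms; and blink, operationalized as
any ocular/frontal sample exceeding 75 uV inside the epoch (an automated
stand-in for manual inspection; threshold configurable). Subjects whose
rejection rate exceeds 30% (strictly) are excluded at the group gate.

## Onset and amplitude scoring

Onset latency is scored on 15 Hz low-passed waves as the earliest time the
wave reaches 50% of its peak (peak searched over 0..800 ms for S-LRP,
-400..+100 ms for R-LRP, configurable), with linear interpolation between
samples; ties resolve to the earliest crossing. Scoring runs on the grand
average and on every leave-one-subject-out grand average (the jackknife).
The leave-one-out scores give a standard error,
\(\mathrm{SE} = \sqrt{\frac{n-1}{n}\sum_i (o_i - \bar o)^2}\), and feed the
group test with the usual correction \(F/(n-1)^2\) (or \(t/(n-1)\)) that
restores the type-I error rate the nearly-identical leave-one-out scores
would otherwise destroy. For the Bayesian repeated-measures analysis, the
leave-one-out scores are first converted to jackknife pseudovalues
\(o^*_i = n\,\bar o - (n-1)\,o_i\), which restores subject-level variance
so the ordinary model applies without the \((n-1)^2\) inflation.

Mean amplitude is measured on the wide-band (0.05--100 Hz) waves — the
15 Hz filtered copy is refused by `mean_amplitude()`, and double filtering
is refused by `lowpass_for_onset()`, so the constraint is structural rather
than conventional. Amplitude measurement windows have *no default* and must
be supplied in the configuration: no defensible canonical window exists,
and a silent default would manufacture one.

## Statistics

`rm_anova_gg()` is the one-way within-subject F with Greenhouse-Geisser
correction (epsilon from the double-centered covariance of condition
scores; both dfs multiplied by epsilon) and partial eta squared.

The Bayesian layer provides three default Bayes factors:

* `bf_ttest_paired(t, n, cauchy_scale)` — JZS BF from sufficient
  statistics, Cauchy(0, 0.707) prior on the standardized effect by
  default. The convention-default scale is used because the printed
  t-test BFs of the motivating design are reproduced by it to within the
  rounding of the printed t.
* `bf_correlation(r, n, beta_width)` — exact correlation BF under a
  stretched beta prior (width 1 = uniform on (-1, 1)), via the closed-form
  hypergeometric expression; tests cross-check it against trapezoid
  quadrature of the exact sampling density with the hypergeometric factor
  evaluated through its Euler integral — a fully independent route.
* `bf_rm_anova(x, r_fixed = 0.5, r_random = 1)` — one-way repeated-measures
  BF with g-priors on standardized effects (condition effect projected on
  orthonormal sum-to-zero contrasts sharing one g; subject random effect
  sharing another), marginal likelihoods by the Woodbury identity, and the
  two-dimensional g-integral evaluated by Gauss-Legendre quadrature in
  log g. Quadrature is the default because it is deterministic — rerunning
  a report reproduces it byte for byte; a seeded Monte Carlo sampler
  (10,000 draws by default) is retained as a cross-check. The r-scale for
  covariates (0.354) appears in the prior specification for interface
  completeness but is unused: the design has no covariates.

No multiple-comparison correction is applied anywhere, matching the
Bayesian reporting convention the pipeline mirrors. `bf_label()` applies
the conventional evidence bands (3, 10, 30) in whichever direction the
Bayes factor favors.

A property worth stating because it is counterintuitive: literally
duplicating a null dataset does **not** increase the evidence for the null.
Exact duplicates make the sampled condition deviations look more precisely
resolved, which moves the Bayes factor toward the alternative. Evidence for
a true null accumulates with *fresh* data — larger simulated null samples
give systematically larger BF01 — and that is the property the test suite
asserts.

## Numerical choices and degenerate inputs

* Onset criterion crossings interpolate linearly between samples; a wave
  that never reaches the criterion raises an error naming the subsample.
* `rm_anova_gg()` refuses zero within-subject error variance rather than
  returning an infinite F.
* The hypergeometric series is summed to a relative tolerance of 1e-14; its
  argument is `r^2 < 1`, where the series converges.
* Interpolation refuses C3/C4; EOG regression drops flat EOG channels and
  errors on rank-deficient (collinear) EOG sets.
* EDF/BDF export uses integer physical bounds so the channel gain survives
  the 8-character header fields exactly; data round-trip to quantization
  accuracy (16-bit for EDF, 24-bit for BDF).

## Validation problem sizes

The test suite validates at sizes chosen to make each question answerable
while keeping the whole suite runnable on a laptop: parameter recovery uses
20 simulated subjects with 100 trials per condition at 256 Hz, replicated
over 20 seeds, asserting onset recovery within 2 samples and mean-amplitude
recovery within 10% against the analytic template truth; the jackknife
adjustment is calibrated on 500 null replicates of 8 subjects; the Bayesian
null behavior uses dozens of replicates at 8--24 subjects. The statistics
layer itself is size-independent (sufficient statistics in, Bayes factor
out), so the printed-value reproductions run at exactly the published
(t, r, n).

## Known limitations

* The synthetic noise is white; estimator variances on real (autocorrelated)
  EEG will be larger than the recovery tests suggest.
* EOG regression assumes linear, stationary propagation; it does not remove
  saccadic spike potentials or muscle artifact.
* The R-LRP inherits RT variability by construction; the simulator's
  stimulus-locked template means response-locked recovery is smeared by the
  RT distribution, as it is in real data.
* `bf_rm_anova()` covers the one-way within-subject case only; multi-factor
  designs (and hence enforced-marginality model sets) are out of scope.
* EDF+/BDF annotation channels are not written; events travel in a sidecar
  CSV.
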