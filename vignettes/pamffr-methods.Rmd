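---
title: "Simulating and quantifying myogenic contamination of the frequency-following response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying myogenic contamination of the frequency-following response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamffr)
```

## Overview

The frequency-following response (FFR) is a sustained scalp potential
phase-locked to the periodicity of an auditory stimulus. The postauricular
muscle (PAM) reflex — a vestigial sound-evoked contraction behind the ear —
produces a large transient myogenic potential 12.5–15 ms after each sound
onset. Because PAM motor units can be driven at 100–200 Hz, the individual
pitch pulses of a periodic stimulus each evoke a PAM wavelet; the overlapping
train of wavelets is itself a sustained, phase-locked potential occupying the
same part of the EEG spectrum as the FFR. When the reference electrode sits
on the mastoid, directly over the muscle, the "FFR" that is measured is a
mixture of neurogenic response and myogenic artifact.

`pamffr` packages both sides of this problem: a generator that synthesizes
two-channel evoked recordings with a *known* artifact/neural composition, and
the full measurement-and-inference pipeline that an electrophysiologist would
run on real data. Because the generator's composition is known, every stage
of the pipeline can be validated against planted ground truth.

## The recording model

All signals are sampled at 20 kHz in microvolts, epoched from stimulus onset
(clicks: 0–24.7 ms; trains: 0–127 ms), with a 50–3,000 Hz passband. Two
montages are modeled: mid-forehead referenced to the ipsilateral mastoid
(picks up PAM) and to the 7th cervical vertebra (distal to the muscle,
PAM-free).

For a subject with neural gain $g$, PAM size $P$ (peak-to-peak, µV) and gaze
angle $\theta$:

* **click runs** — mastoid: $g \cdot \mathrm{ABR}(t) + P\,g(\theta)\,w(t)$;
  neck: $g \cdot \mathrm{ABR}(t)$. The ABR template is three positive
  Gaussian deflections at the subject's wave I/III/V latencies (defaults
  1.5/3.5/5.5 ms, sub-µV). The transient ABR appears with the same polarity
  in both montages, so channel subtraction cancels it and isolates the PAM
  wavelet $w(t)$ — mirroring how the artifact is isolated in practice.
* **train runs** — mastoid:
  $(P\,g(\theta)\,w \ast h)(t) - g \cdot u(t)$; neck: $g \cdot u(t)$, where
  $h(t) = \sum_n \delta(t - nT)$ is the stimulus pulse train ($T = 1/F_0$,
  first pulse at $t = 0$ so the derived response aligns with the epoch
  origin) and $u(t)$ is the sustained neurogenic FFR. The sign flip of the
  neural component between montages reproduces the ~180° phase shift seen
  between mastoid- and neck-referenced sustained responses.

Per-sweep noise is Gaussian and exactly band-limited to 50–3,000 Hz
(synthesized in the frequency domain), with sd `noise_sd` µV.

### The PAM wavelet

The wavelet is a biphasic difference of Gaussians (width 1.6 ms, lobe
separation 2.5 ms), placed so that its *band-passed* maximal positive
deflection falls at the subject's PAM peak latency (drawn from 12.5–15 ms)
and scaled so that its band-passed peak-to-peak equals
$P \cdot g(\theta)$. Amplitudes are defined after filtering because real
recordings are hardware-filtered online: every published artifact amplitude
is a post-filter measurement, and defining the planted value on the same
side of the filter makes noise-free parameter recovery exact.

The wavelet width matters scientifically: its magnitude spectrum at 200 Hz
is about 0.3 of that at 100 Hz, steep enough that the artifact's
contribution to the FFR declines with stimulus frequency *even though* a
200 Hz train delivers twice as many pulses per unit time. This reproduces
the observation that PAM-related FFR contamination weakens at higher F0s and
motivates high-F0 stimuli as a mitigation.

### Gaze dependence

PAM contraction is potentiated by rotating the eyes toward the stimulated
ear. The gain curve is
$g(\theta) = f + (1 - f)(|\theta|/70)^{p}$, pinned to 1 at ±70° and to the
floor $f$ at midline, symmetric in $\theta$. Each subject draws a private
exponent $p$ (log-normal around the cohort value): listeners differ in how
steeply lateral gaze recruits the muscle, while the maximal-gaze response is
the subject's trait PAM size by construction. The five gaze positions are
−70°, −35°, 0°, +35°, +70° (positions 1–5).

### Run-level muscle variability

Two mean-one log-normal factors make the artifact realistically unstable:

* **muscle-state drift** (`pam_state_sd`): each subject × gaze × stimulus
  run scales its PAM amplitude by a fresh draw — tonic muscle tension varies
  between recording runs. This is why a click-run PAM measurement predicts,
  but does not perfectly determine, the artifact in the FFR run (the
  across-subject correlation lands near 0.72 rather than ~1).
* **per-pulse motor-unit jitter** (`pam_pulse_jitter_sd`): within a train
  run, the wavelet evoked by each pitch pulse is scaled by its own draw,
  fixed across sweeps (it survives ensemble averaging — systematic
  per-position deviations, not trial noise). The modulated train is then
  rescaled to the steady-state RMS of the unmodulated one, so jitter changes
  the *shape* of the sustained artifact but not its run-level amplitude —
  amplitude is governed by the state factor alone. This shape mismatch is
  the principal reason the linear superposition model explains only ~50% of
  the measured FFR variance, as it does in real recordings, while
  amplitude-based statistics (gaze ratios, PAM–FFR correlations) are
  unaffected. Trial-to-trial PAM variability within a run is deliberately
  not modeled; habituation across a session is out of scope.

### The neurogenic FFR

The sustained neural component $u(t)$ is a harmonic stack at the stimulus
F0 (harmonics up to 850 Hz, amplitudes $\propto h^{-0.8}$, fixed scattered
phases), delayed by an 8 ms neural lag and gated with 5 ms raised-cosine
ramps over the 100 ms stimulus. It is deliberately *not* an iterated click
ABR: if the sustained neural response were exactly the onset response
repeated at F0, convolving the subject's own click response with the pulse
train would reproduce the measured FFR perfectly and the superposition model
could never score below $r = 1$. Real FFRs carry phase-locked structure that
the onset transient does not predict; a distinct sustained template is the
simplest generative expression of that fact. Its scale is set by
`snr_neural_pam`, the RMS ratio of the neural component to the convolved
artifact of a cohort-mean-sized PAM at maximal gaze.

### Cohort structure

Musical training is zero-inflated (35% exact zeros) with a right-skewed
gamma tail capped at 23 years, calibrated to population mean 6.5 and sd
7.3 years; it is a monotone transform of a latent standard normal. Log PAM
size follows the standardized path `a_music_pam` from training and maps to
a log-normal clipped to [0.18, 9.7] µV; log neural gain follows
`b_music_neural`. Both paths are planted correlations only — the package
takes no position on *why* trained musicians show larger reflexes (eye
movement habits and neck muscle tension are both candidates).

## Measurement pipeline

Preprocessing applies a zero-phase (forward–backward) 2nd-order Butterworth
high-pass at 50 Hz, low-pass at 3,000 Hz, and a narrow 2nd-order band-stop
at 60 Hz (2 Hz wide, Q = 30), with odd-reflection end padding so short
epochs are not dominated by start-up transients. Zero-phase filtering is
chosen so latency measurements are unbiased. Rejection excludes any sweep
with a sample beyond ±50 µV, applied to the raw sweep (hardware rejects
online, before filtering and averaging); survivors are averaged
arithmetically.

Metrics: PAM peak-to-peak and peak latency are measured on the
channel-subtraction waveform in an 8–18 ms window; FFR RMS on 10–110 ms
(the 100 ms stimulus plus ~10 ms neural transmission — the epoch-level RMS
window is a package choice, documented here because reasonable alternatives
exist); onset latency as the maximal positive deflection in 6–12 ms;
spectral amplitudes at the bin nearest F0 and harmonics from a
rectangular-tapered window zero-padded to 1 Hz resolution (amplitude
normalized: a sinusoid of amplitude A reads A). Cross-correlation is
Pearson-at-lag over a symmetric ±20 ms search, reporting the signed maximum.

### The convolution model

`derive_ffr()` convolves a transient source — by default the subject's
PAM-contaminated mastoid click response at maximal gaze, alternatively the
isolated PAM — with the stimulus pulse train, truncated to the FFR epoch
with no circular wrap (the physical process is onset-locked).
`score_model()` cross-correlates derived against measured on the common
10–110 ms steady-state window so onset transients do not dominate, and
reports $r$, its lag, and $R^2 = r^2$.

### Inference

The gaze analysis uses within-subject orthogonal polynomial contrasts
computed for the actual unequal angle spacing (Gram–Schmidt on
$\{1, \theta, \theta^2\}$), with a one-sample t-test of per-subject contrast
scores (df = n − 1). A U-shaped (midline-minimum) amplitude profile loads on
the quadratic contrast. This subject-level contrast procedure replaces a
mixed-model ANOVA with fractional degrees of freedom: it tests the same
planted pattern with machinery that is fully specified here.

The individual-differences analyses (correlation, regression, mediation)
operate on the aggregated subject × gaze table built by
`aggregated_table()`: FFR RMS keeps its per-gaze variation, while the PAM
regressor is the subject's *trait* artifact strength — the isolated-PAM
peak-to-peak at maximal gaze, replicated across that subject's rows. The
artifact-strength measure is defined at position 5 because that is where
isolation is cleanest; pairing per-gaze PAM with per-gaze FFR instead would
couple the two measures through the shared gaze profile and overstate the
pooled association. Rows within a subject are not independent;
reported degrees of freedom follow the naive row count, which matches
common practice for this design and is flagged here as a caveat.

Mediation fits OLS paths a (X→M), b (M→Y|X), c (total), c′ (direct); the
identity c = c′ + a·b holds to numerical precision and is verified
internally. The indirect effect a·b is tested by the Sobel statistic
$z = ab / \sqrt{b^2\,\mathrm{se}_a^2 + a^2\,\mathrm{se}_b^2}$ and by a
percentile bootstrap over case resamples (default 1,000). Criteria flags
follow the classical scheme: (i) X predicts Y, (ii) X predicts M,
(iii) the direct path loses significance controlling M (full mediation);
partial mediation = indirect effect reliable while the direct path
survives.

Two calibration caveats that users should understand. First, on the
gaze-aggregated table the case-resampling bootstrap treats the 100 rows as
independent, but X and M are constant within each of the 20 subjects; under
a null music→PAM path the 95% percentile interval of a·b then excludes zero
in roughly half of null simulations — the same pseudo-replication that
inflates the naive row-count degrees of freedom. Inferences from the
aggregated table should be read as descriptive of that (conventional)
design, not as subject-level inference. Second, even on the clean
subject-level design (one independent row per listener), the percentile
interval at n = 20 excludes zero in about 7% of null cohorts rather than
5% — the known small-sample behavior of percentile intervals for a product
of coefficients, aggravated here by the heavy-tailed mediator. With 100
independent rows the same bootstrap is nominally calibrated (measured 6%
exclusion). Mediation conclusions at n = 20 should therefore lean on the
Sobel test and the CI jointly, not the CI alone.

## Calibration of the generator defaults

The study conditions are fixed by the shipped `effect_structure()` defaults.
They were frozen once, by a seeded coordinate search
(`scripts/calibrate.R`) over the generative parameters until the *pipeline's
measurements* on fresh default cohorts (n = 20, 2,000-sweep averages)
reproduce the reference statistics: mean isolated-PAM peak-to-peak 2.38 µV;
PAM–FFR correlation 0.72 at maximal gaze; 3–4× gaze amplification of
mastoid FFR RMS with a flat neck channel; convolution-model mean r = 0.71
and mean R² ≈ 50%; music–FFR correlation 0.34 with partial correlations
0.49 (PAM|music) and 0.21 (music|PAM); Sobel z ≈ 2.72. Search seeds were
separate from the verification seeds. Two details are worth recording:

* the latent log-PAM mean is set so the *measured* cohort mean is 2.38 µV;
  the planted mean is ~2.22 µV because a max-minus-min measurement on signal
  plus residual averaged noise is biased upward by ~0.13 µV, and the
  reference value is itself a measurement;
* the per-sweep noise sd (2.5 µV) is a design choice — no per-sweep noise
  level is available to match — set so that 2,000-sweep averages have
  FFR-like SNR while chance rejection of clean sweeps is negligible.

## Simulation modes and problem sizes

`simulate_recordings()` defaults to *averaged mode*: each ensemble average
is synthesized directly as signal plus band-limited noise with sd
`noise_sd`/√`n_sweeps`, which is distributionally identical to averaging
`n_sweeps` clean simulated sweeps (averaging is linear, and at the default
noise level the ±50 µV criterion never triggers on clean sweeps). Sweep
mode generates and rejects raw sweeps explicitly and is used to validate the
equivalence and the rejection logic. The shipped replication experiments
use 25 cohorts of 20 subjects with 2,000-sweep averages; the bootstrap
calibration study uses 500 null cohorts with a reduced recording design
(clicks at maximal gaze only, mastoid FFRs only) — sizes chosen as the
smallest at which the seed-averaged statistics are stable.

## What the synthetic cohorts do and do not show

Passing the replication suite shows the pipeline is internally consistent
and that the planted mechanism — a gaze-scaled, training-correlated myogenic
wavelet iterated at F0 — reproduces the full observed statistical pattern.
It does not show that real FFRs contain *only* these components: real EEG
has 1/f background, alpha rhythms, cortical phase-locked sources,
attention- and state-dependent amplitude drift, and eye-tracking error,
none of which are modeled. The generator also plants no mechanistic
explanation for the training–PAM association (tension vs. oculomotor
habits), only the correlation itself. Conclusions about real recordings
should rest on the measurement tools; the synthetic cohorts are a testbed,
not evidence about human physiology.

## Numerical notes and degenerate inputs

* Filtering is linear and shift-invariant away from epoch edges; planted
  amplitudes are defined post-filter, so noise-free recovery is exact to
  measurement precision. Filtering-then-convolving differs from
  convolving-then-filtering only through edge padding (relative error
  < 0.5% in steady state).
* `onset_latency()` returns `NA` with a warning on flat windows;
  `xcorr_max()` and the correlation functions refuse zero-variance input;
  `reject_and_average()` errors when every sweep is rejected, naming the
  threshold.
* Impulse counts use `ceiling(d·F0)` with pulses strictly before the train
  end; a train shorter than one period is an error, and sub-sample click
  widths are refused with the minimum representable width in the message.
* All randomness flows through explicit integer seeds (`withr::with_seed`);
  identical seeds give bit-identical cohorts, sweeps, averages and bootstrap
  intervals.
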