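# pamffr

Simulation and analysis of postauricular-muscle (PAM) contamination of the
auditory frequency-following response (FFR).

## The problem

The FFR is a scalp-recorded evoked potential phase-locked to the periodicity
of an auditory stimulus, widely used as a neural index of complex sound
encoding and of experience-dependent plasticity (musicianship, language
experience, auditory disorders). The PAM is a vestigial startle reflex behind
the ear: a brief sound evokes a large myogenic potential (up to ~10 μV,
peaking 12.5–15 ms post-stimulus) that is picked up by the mastoid reference
electrodes used by much of the FFR literature, and whose size grows when the
eyes are rotated toward the stimulated ear. Because PAM motor units can
follow driving rates of 100–200 Hz, a periodic stimulus evokes a *train* of
overlapping PAM wavelets — a sustained, phase-locked potential that
masquerades as the neurogenic FFR.

`pamffr` provides, for methodologists and electrophysiologists who want to
study or guard against this confound:

* **stimulus construction** — clicks and periodic click trains
  `h(t) = Σₙ δ(t − nT)` with `T = 1/F0`;
* **a synthetic cohort generator** — two-channel (mastoid / neck-referenced)
  epoched recordings with planted ABR waves (I/III/V at 1.5/3.5/5.5 ms), a
  gaze-dependent PAM wavelet, a sustained neurogenic FFR, per-sweep
  band-limited EEG noise, and a cohort-level correlation structure linking
  musical training, PAM size and neural gain;
* **preprocessing** — zero-phase 50–3,000 Hz band-pass + 60 Hz notch,
  ±50 μV sweep rejection, ensemble averaging, channel-subtraction PAM
  isolation;
* **metrics** — peak-to-peak and RMS amplitudes, wave latencies, spectral
  amplitudes at F0 and harmonics, normalized cross-correlation with lag
  search;
* **the convolution (superposition) model** — derives an FFR as
  `FFR_deriv(t) = (source ∗ h)(t)`, the subject's PAM-contaminated click
  response iterated at the stimulus F0, and scores it against the measured
  FFR (`r`, lag, `R²`);
* **inference** — within-subject orthogonal polynomial gaze contrasts,
  Pearson and partial correlations, OLS regression with variance inflation
  factors, and bootstrap Sobel mediation analysis of the
  music → PAM → FFR path.

## Worked example

```r
library(pamffr)

cohort <- sample_cohort(n = 20, seed = 1)             # 20 synthetic listeners
rec    <- simulate_recordings(cohort, seed = 500001)  # 2,000-sweep averages
mt     <- metrics_table(rec)                          # subject x gaze x channel

# gaze amplification of the mastoid-referenced FFR (uV RMS by gaze position)
mast <- subset(mt, channel == "mastoid" & f0 == 100)
round(with(mast, tapply(ffr_rms, gaze_position, mean)), 3)
#>     1     2     3     4     5
#> 0.890 0.588 0.275 0.618 0.930
# >3-fold larger at +/-70 degrees than at midline; the neck channel is flat:
neck <- subset(mt, channel == "neck" & f0 == 100)
round(with(neck, tapply(ffr_rms, gaze_position, mean)), 3)
#>     1     2     3     4     5
#> 0.260 0.259 0.259 0.259 0.259

# PAM size predicts FFR strength across listeners at maximal gaze
g5 <- subset(mast, gaze_position == 5)
correlate(g5, "pam_p2p", "ffr_rms")$r
#> [1] 0.9031136

# the superposition model: how much of the FFR is iterated PAM?
cohort_model_fit(rec, f0 = 100, gaze_position = 5)
#> <cohort_model_fit> n = 20, mean r = 0.733 (sd 0.078), mean R^2 = 54.2% [source: contaminated_abr]

# mediation: does PAM carry the music-FFR association?
agg <- aggregated_table(mt)                           # subject x gaze rows
mediate(agg, n_boot = 1000, seed = 900001)
#> <mediation_result> n = 100: a = 0.0921, b = 0.2128, c = 0.0409, c' = 0.0214
#>   Sobel z = 3.56 (p = 0.000375), 1000-resample 95% CI of a*b: [0.0025, 0.0407]
```

On this cohort, iterating each subject's own PAM-contaminated onset response
at the stimulus F0 explains about half the variance in their measured FFR,
FFR amplitude more than triples when gaze is directed toward the recorded
ear (while the neck-referenced channel is gaze-invariant), and the
training→FFR association carries a significant indirect path through PAM
size. Single-cohort statistics are noisy at n = 20 — seed-averaged values
(25 cohorts) are the stable quantities and are what `scripts/acceptance.R`
reports.

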