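---
title: "Event-related phase-locking networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-related phase-locking networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvnet)
```

## The analysis problem

In a pre-cued reaction-time (CNV-type) paradigm, a directional warning
stimulus S1 is followed at a fixed 3.2 s delay by an imperative stimulus
S2 that triggers a lateralized button press. Theta-band (4–7 Hz) phase
synchronization between scalp regions rises transiently after each
stimulus, and the structure of that transient network — how strongly
frontal, central, parietal and occipital areas lock to each other —
carries information about sensorimotor integration. `plvnet` implements
the full chain from epoched multichannel recordings to group-level
network statistics:

1. **Phase extraction.** Complex Morlet wavelets (default 5 cycles) at
   1-Hz steps across the band give instantaneous phase
   $\varphi_i(t, n)$ per channel $i$, trial $n$ and frequency.
2. **Phase-locking value.** For a channel pair $(i, j)$,
   $\mathrm{PLV}_{ij}(t) = \bigl|\tfrac1N \sum_{n=1}^{N}
   e^{-\mathrm i(\varphi_i(t,n) - \varphi_j(t,n))}\bigr|$ — the modulus of
   the across-trial mean unit phasor of the phase difference, 1 for a
   perfectly consistent phase relation and $\approx 1/\sqrt{N}$-scale
   noise for random phases.
3. **Baseline normalization.** Event-related change is isolated as
   $\mathrm{rPLV}(t) = (\mathrm{PLV}(t) - \bar b)/\bar b$, with $\bar b$
   the mean PLV over the pre-S1 baseline window [−3700, −3200) ms.
4. **ROI networks.** The 465 electrode pairs of a 31-electrode montage are
   averaged into a symmetric 6×6 area matrix (DLPFC, SMA/PMA, M1, S1,
   PPC, POC; within-area means on the diagonal), whose 21 unique entries
   form the per-subject feature vector.
5. **Graph summaries.** Windowed rPLV also defines a weighted electrode
   graph; global efficiency
   $E_\mathrm{glob} = \frac{1}{N(N-1)}\sum_{i \ne j} 1/L_{ij}$ and the
   average clustering coefficient summarize integration and segregation.
6. **Group layer.** Euclidean distance between group-mean feature vectors
   over time, PCA of connectivity patterns, cross-validated LDA with a
   label-shuffled control, pointwise one-sample increase tests,
   Mann-Whitney U contrasts with Benjamini-Hochberg correction, and
   OLS regressions of behavior on efficiency.

## The synthetic cohort: what it emulates

Real cohorts of this kind are not publicly distributable, so the package
ships a generator whose output has *known* ground truth; every downstream
claim is tested as parameter recovery against it.

Each trial carries one latent theta oscillator with frequency drawn
uniformly in 4–7 Hz (redrawn per trial, so the band is non-stationary and
no narrowband artifact accumulates) and a uniform random phase. The
hierarchy then has two von Mises coupling levels:

* each **area** receives a phase offset around the global oscillator,
* each **electrode** a further jitter around its area,

both with concentration $\kappa(t)$ from the event-locked coupling
profile: $\kappa_\mathrm{base}$ everywhere except the 500 ms windows
after S1 and S2, where $\kappa_\mathrm{event}$ is added. A purely
area-local oscillator model would leave between-area phase relations
unmodulated by the stimuli; the shared top-level oscillator is what makes
*network-wide* synchronization transients — and their group differences —
expressible. Within-area pairs differ by two electrode jitters (expected
asymptotic PLV $[I_1(\kappa)/I_0(\kappa)]^2$, a known monotone function
of $\kappa$); between-area pairs additionally accumulate two area offsets
(fourth power), so within-area coupling exceeds between-area coupling at
every $\kappa$, as in scalp data.

The group effect is a single multiplicative deficit: for the patient
group ("TS") the post-S1 event gain is reduced by the fraction
`group_deficit_s1`, while the post-S2 window is untouched. Per subject,
the event gains of the two windows are scaled by independent lognormal
factors (`subject_sdlog`), and each trial's reaction time is
`rt_intercept + rt_slope * scale_S2 + N(0, rt_sigma)` — so the injected
post-S2 coupling scale, which drives measurable network efficiency, also
drives behavior, giving the efficiency–RT regression a recoverable
target. Background activity is spectrally shaped Gaussian noise with
power density $\propto 1/f$ (`noise_exponent`), added at a configurable
oscillation-to-noise RMS ratio. Behavioral errors are injected as
anticipatory presses (rate `anticipatory_rate`) and wrong-side responses
(`error_rate`); a trial enters the EEG analysis only when the response
was correct and within 1.5 s.

Phase jitter is drawn once per (electrode, trial, coupling segment) —
piecewise-constant across the epoch's stimulus-window segmentation rather
than independently per sample. This reproduces the step-like event-locked
PLV transients the analysis targets at a fraction of the sampling cost;
it does *not* emulate continuous phase diffusion within a segment.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| `n_per_group` | 20 | subjects per group |
| `n_trials_per_side` | 50 | trials per response side |
| `fs` | 200 Hz | sampling rate |
| `epoch_span` | −3700..3000 ms | epoch re S2 (1341 samples) |
| `s1_latency` | −3200 ms | warning stimulus onset |
| `kappa_base` | 2 | baseline coupling concentration |
| `kappa_event` | 6 | added concentration, 500 ms post-stimulus |
| `group_deficit_s1` | 0.5 | TS fractional loss of post-S1 gain |
| `noise_exponent` | 1 | 1/f noise slope |
| `snr` | 1 | oscillation/noise RMS ratio |
| `subject_sdlog` | 0.35 | log-SD of subject event-gain scales |
| `rt_intercept`, `rt_slope`, `rt_sigma` | 430, −100, 50 ms | RT model |
| `anticipatory_rate`, `error_rate` | 0.07, 0.05 | behavioral error rates |

$\kappa_\mathrm{base} = 2$ puts baseline within-area PLV near 0.49 and
between-area PLV near 0.24; $\kappa_\mathrm{event} = 6$ lifts them to
roughly 0.88 / 0.77 at the group level before noise. The RT model centers
subject means near 330 ms with a between-subject SD around 35 ms, and
`subject_sdlog = 0.35` makes the post-S2 coupling scale — the RT driver —
strong enough relative to PLV estimation noise that the efficiency–RT
regression recovers the injected negative slope reliably at n = 20 per
group. These are power-oriented choices for validation, not estimates of
any real cohort's effect sizes; absolute rPLV and efficiency values are
comparable only within this artifact.

### What passing tests do and do not show

The generator produces CSD-like, artifact-free, stationary-noise epochs
with exactly one oscillatory source hierarchy. Passing recovery tests
demonstrates that the *pipeline* detects coupling deficits, efficiency
differences, and RT links of known size at the study's sample size — not
that such effects exist in, or generalize to, real recordings. Volume
conduction, eye/muscle artifacts, non-stationary noise floors and
between-subject montage variation are all outside the generated data.

## Numerical and design choices

* **Wavelet cycles.** Default `n_cycles = 5`: at 4 Hz this gives a
  temporal SD of ~0.2 s — transients on the 500-ms window scale remain
  resolvable while 1-Hz bins stay separable. Configurable.
* **Aggregation order.** rPLV is computed per 1-Hz bin and then averaged
  across bins, keeping each bin's baseline normalization exact; the
  left- and right-hand conditions are baseline-normalized separately and
  averaged afterwards, before any group statistics.
* **Windows.** All windows are half-open `[start, end)` in ms relative
  to S2; a sample at time $t$ belongs to the window via
  `floor((t - t0) fs / 1000)`, so adjacent 100-ms subwindows never share
  samples and window means are exactly additive.
* **Edge handling.** Samples within the wavelet half-support (3 temporal
  SDs) of an epoch edge are flagged invalid. The baseline window itself
  starts at the epoch edge — inherent to the epoch geometry, which
  allots exactly 0.5 s before S1 — so baseline PLV carries edge
  attenuation from the zero-padded convolution. Both baseline and event
  windows are affected multiplicatively and rPLV is a ratio, so the bias
  largely cancels; the `valid` flags report it honestly.
* **Degenerate amplitudes.** Coefficients with modulus below `1e-12`
  contribute a zero phasor instead of an undefined phase (an all-zero
  channel yields PLV contributions of 0, never NaN). A pair whose
  baseline mean PLV falls below `eps = 1e-6` is flagged unusable and
  excluded rather than divided by.
* **Negative weights.** Windowed rPLV can be negative
  (desynchronization); path lengths require nonnegative weights, so
  negative values are clipped to 0 (edge absent) when building graphs.
* **Efficiency modes.** `"binary"` (hop counts on the positive-weight
  skeleton) mirrors the common library default that ignores weights;
  `"weighted"` uses distance $1/w$. On synthetic data nearly all windowed
  rPLV means are positive, so the binary skeleton is complete and binary
  efficiency saturates at 1 — group effects live in the weighted mode
  there, and weighted efficiency scales linearly with a common weight
  factor (documented, tested). Both modes are computed everywhere.
* **Classifier protocol.** Folds hold out exactly one subject per group
  (chance stays at 50 %); the training set alone defines the z-scoring
  and the top-10 ANOVA-F feature selection (ties broken toward the lower
  feature index); the discriminant uses the pooled within-class
  covariance with a `1e-6` diagonal ridge for singular cases. The
  shuffled control permutes training labels independently within each
  fold. No hyperparameter exploration on test data is performed.
* **PCA standardization.** Features are centered/scaled on the pooled
  (concatenated across groups and time) data; zero-variance features are
  dropped with a warning since they cannot be scaled.
* **Pointwise tests.** One-sided (greater) one-sample t tests, since the
  question is an event-related *increase* in phase locking; the map is
  exploratory and deliberately uncorrected, while scalar contrasts and
  regression families are BH-adjusted.
* **Mann-Whitney reporting.** U and p come from `stats::wilcox.test`
  (exact for small tie-free samples); the Z score is the tie-corrected
  normal approximation without continuity correction, and the effect
  size is $r = |Z|/\sqrt{n_1 + n_2}$.
* **RT filters.** Reaction times outside the open interval
  (150, 1500) ms are excluded from behavioral summaries; anticipatory
  presses (between S1 and S2) are counted separately and never
  contribute an RT.
* **Randomness.** One root seed (`config$seed`) drives everything:
  per-subject seeds are derived from it, and the bulk Gaussian noise
  stream (a dedicated C++ Mersenne Twister, used because millions of
  draws per subject dominate generation cost otherwise) is seeded from
  the per-subject R stream. Identical seeds give byte-identical cohorts.

## Problem sizes used in the validation experiments

The recovery experiments in the test suite run 20 seeded replicates of
the full design — 20 subjects per group, 50 trials per side, 31
channels, 4 frequency bins — for the deficit arm and 20 for the null
arm. Two package-level reductions keep them desk-sized without touching
those study conditions: epochs are generated only out to the last sample
any analysis window needs (cue-only spans where post-S2 data is unused),
and PLV is evaluated on a 25-ms grid (`sample_step = 5`) within the
windows; the windowed means average a curve that is smooth on the 100-ms
scale, so the grid choice is immaterial to the window statistics. A
single full-epoch subject (1341 samples, 100 trials, every window sample
evaluated) takes a few seconds, so a complete 40-subject run remains a
matter of minutes on one CPU.

## Known limitations

* The generator's effect parameterization is chosen for statistical
  power (the source conditions publish no effect sizes for simulation),
  so absolute connectivity values are not calibrated to any cohort.
* Binary-mode efficiency is non-informative on data whose windowed rPLV
  is all-positive (skeleton saturates); use the weighted mode there.
* The epoch-edge position of the baseline window biases absolute PLV
  levels there; rPLV mostly cancels it but does not remove it exactly.
* No artifact simulation, no volume-conduction forward model, no source
  projection: the pipeline assumes cleaned, CSD-transformed input.
* Importers for vendor formats are not included; recordings must be
  provided in the package's container (float32 + JSON sidecar) with ROI
  labels matching the montage (PO1/PO2 may need remapping from PO3/PO4).
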