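---
title: "Respiratory-rate estimation from PPG: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory-rate estimation from PPG: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgrr)
```

## The problem

A photoplethysmographic (PPG) signal — whether from a finger sensor or
extracted remotely from face video — is dominated by the cardiac pulse, but
breathing leaves three distinct marks on it:

* **RIIV** (respiratory-induced intensity variation): intra-thoracic pressure
  swings modulate venous return, so the whole waveform baseline rises and
  falls with breathing.
* **RIAV** (amplitude variation): stroke-volume changes modulate the height
  of each pulse.
* **RIFV** (frequency variation): respiratory sinus arrhythmia speeds the
  heart on inspiration and slows it on expiration, so beat-to-beat intervals
  oscillate at the breathing frequency.

`ppgrr` estimates respiratory rate (RR, breaths/min) from a single PPG
channel by three method families and provides the statistical machinery to
compare them: morphological extraction of the three RIV waveforms with
mean/median/PCA fusion, empirical mode decomposition (EMD), and singular
spectrum analysis (SSA). In every branch the final step is the same: the RR
is the frequency of the most powerful periodogram peak inside a respiratory
search band adapted to the estimated heart rate.

## Signal model and pipeline

A recording `x(t)` of length `T` samples is split into `S = floor((T−M)/K)+1`
windows of `M` samples shifted by `K` samples (defaults: 30 s windows, 1 s
shift). Per window:

1. **Pre-processing.** A zero-phase Butterworth band-pass. The
   decomposition branches (EMD, SSA) use the default band 0.18–1.0 Hz, which
   suppresses the cardiac fundamental while keeping the respiratory
   baseline. The morphological branch must *see* the cardiac pulses it
   segments, and must not remove baseline wander slower than 0.18 Hz (that
   wander *is* the RIIV of slow breathers), so it uses 0.08–2.5 Hz by
   default (`pipeline_config(ims_band=)`). Filtering is forward-backward:
   zero phase distortion matters because the RIFV channel is built from
   landmark *timing*.
2. **Method.** IMS, EMD or SSA (below).
3. **Post-processing.** The artifact-reduction operator
   Π(x) = Deriv(Spline(x)): a cubic spline through the points, evaluated as
   its analytic first derivative on a uniform grid (8 Hz for event series).
   Differentiation suppresses slow drift; spline evaluation converts
   beat-indexed series to uniformly sampled ones.
4. **RR picking.** Periodogram of the mean-removed series (rectangular
   window, 4× zero-padding so the frequency grid does not quantize the
   estimate), peak restricted to `[0.1, min(0.6, HR/2)]` Hz, where HR is the
   periodogram peak of the raw window in 0.7–3 Hz. If no credible cardiac
   peak exists the fixed screening band `[0.1, 0.5]` Hz is used. The HR/2
   cap keeps the search below the first cardiac harmonic; 0.6 Hz
   (36 breaths/min) bounds plausible resting rates. Per video, window
   estimates are combined by their median.

## Incremental merge segmentation (IMS)

The window is reduced to strided points `y_k = x(mk)` (stride `m` chosen to
keep ≈ 25 points/s). The slope of each sub-segment is computed, and the
central point of every triplet whose two slopes share a sign is deleted,
repeatedly, until only turning points survive — monotone runs merge into
single segments whose endpoints are pulse extrema. Two refinements follow as
the "peak detection" stage:

* **Prominence screen** (`min_prominence`, default 0.3): adjacent max/min
  pairs whose excursion is below 0.3× the mean excursion are ripples (noise
  or dicrotic wiggles riding on a pulse) and are removed, merging the
  flanking extrema. The mean — not the median — is the reference, so the
  screen still works when ripples outnumber genuine pulse swings, and it
  grows as ripples are removed, so the iteration converges.
* **Parabolic refinement** (`refine`): each extremum's time and value are
  moved to the vertex of the parabola through it and its two neighbours. At
  25 Hz video rate the ±half-sample timing quantization (±20 ms) is
  otherwise on the same scale as respiratory sinus arrhythmia itself.

Setting `min_prominence = 0, refine = FALSE` reproduces the bare
slope-merging algorithm, which the test suite checks against an exhaustive
triplet scan.

From the turning points: RIIV = Π(peak values); RIAV = Π(peak minus
immediately preceding trough — the systolic upslope); RIFV = Π(tachogram of
inter-landmark intervals, timestamped at interval midpoints, with intervals
deviating more than 40% from the median discarded as detection artifacts —
standard tachogram screening).

Two RIFV options deserve explanation, because the package's pipeline
defaults deviate from the textbook definition (the *module* defaults do
not):

* **Landmark** (`rifv_landmark`): the classical tachogram uses pulse-foot
  minima. The foot sits in a broad valley whose detected position flips
  between the primary and the dicrotic valley under noise, while the
  systolic peak is the sharpest, highest-SNR landmark in the waveform and
  carries identical beat-timing information. The pipeline therefore uses
  peak intervals (`"maxima"`).
* **Differentiation** (`rifv_differentiate`): the tachogram is already a
  differenced quantity with no baseline trend, so the Π derivative has no
  drift to remove there; what it does do is multiply timing-jitter power by
  ω², which at 25 Hz sampling buries breathing peaks below ≈ 0.2 Hz
  (12 breaths/min) under jitter noise. On simulated recordings at 9
  breaths/min and 10 dB SNR the differentiated tachogram estimate converges
  to ≈ 26 breaths/min (pure jitter), while the resampled-only tachogram
  recovers 9.0. The pipeline therefore applies the spline resampling
  without the derivative to RIFV only; RIIV and RIAV keep the full
  operator.

**Fusion.** The `avg` and `median` estimators combine the three per-channel
RR values arithmetically. `pca` standardizes the three RIV waveforms on a
common grid, takes the first principal component as a fused waveform (sign
oriented to correlate positively with RIIV for determinism), and estimates
RR from its spectrum.

## Empirical mode decomposition

One intrinsic mode function (IMF) is extracted by sifting: cubic-spline
envelopes through the local maxima and minima, subtract the envelope mean,
repeat until the summed squared relative change between consecutive
candidates, Σ (d_i − d_{i−1})² / d_{i−1}², falls to 0.1 (evaluated from the
second iteration; denominator guarded by ε = 10⁻¹²; at most 50 iterations).
Envelope splines mirror-extend the outermost two extrema about the window
ends to damp end swings. Decomposition peels IMFs off the running residual
until the residual is monotone or has fewer than two maxima or minima,
capped at four IMFs. The construction is purely subtractive, so IMFs plus
residual reconstruct the window to machine precision — asserted at 10⁻⁸ in
the tests.

Per-IMF RR estimates are produced for the first three IMFs; `RR_EMD` is the
per-IMF estimate whose in-band spectral peak has the greatest power (all
extracted IMFs compete). "Greatest power" rather than "highest frequency"
was chosen deliberately: a max-frequency rule would systematically favour
high-frequency artifacts; the same rule is applied to SSA for consistency,
with `select = "frequency"` available.

## Singular spectrum analysis

The window is lag-embedded into the `L × (M−L+1)` Hankel trajectory matrix
(default `L = 17` samples, the scale at which a ≈ 1 Hz cardiac oscillation
at 25 Hz occupies a two-dimensional subspace; `L` is exposed because no
universal best value exists). SVD yields singular triplets; each rank-1
elementary matrix is projected back to a series by anti-diagonal averaging
(Hankelization). No component grouping is performed — every triplet is
reconstructed individually — and the first three components feed per-EOF RR
estimates; `RR_SSA` again takes the most powerful in-band peak. EOF signs
are fixed by making each EOF's largest-magnitude entry positive, so results
are deterministic.

## Quality control of respiratory references

Respiratory ground-truth traces are screened before being trusted: 0.1–0.5
Hz second-order zero-phase Butterworth, 5 s trimmed from each end
(filter start-up transients otherwise inflate the trough statistics),
normalization to [−1, 1], then peak/trough detection with ≥ 1 s separation
(half the period of the band's upper edge) and a midline height floor
(band-pass ringing in breathing pauses must not count as breaths). The
screen computes σ₁ = SD of successive peak-to-peak intervals (seconds) and
σ₂ = SD of trough heights (normalized units) and accepts only recordings of
at least 30 s with σ₁ ≤ 1 and σ₂ ≤ 0.2. The σ₁ threshold is interpreted in
seconds — the only unit in which 1 is a meaningful breath-interval
dispersion.

## Evaluation framework

Per-estimator error populations (one value per video) are compared by:

* MAE and RMSE (MAE ≤ RMSE always; property-tested).
* Bland–Altman agreement: bias, 1.96·SD limits of agreement, and an OLS
  slope of differences on means to expose proportional bias.
* A Shapiro–Wilk (per population) and Levene (across populations) gate; any
  normality rejection sends the analysis down the nonparametric path.
* Friedman omnibus test on within-video ranks, Nemenyi pairwise p-values
  from the Studentized range distribution, and the critical difference
  CD = q_{α,k}/√2 · √(k(k+1)/6N) for CD diagrams.
* A robust effect size between error populations: difference of medians
  over the pooled consistency-scaled MAD (1.4826·MAD, estimating σ under
  normality), labelled negligible/small/medium/large at |γ| thresholds
  0.2/0.5/0.8. The exact variant of this median-based statistic is not
  standardized in the literature; this package's formula is documented here
  and isolated in `akinshin_gamma()`, and the 0.2/0.5/0.8 thresholds
  reproduce all 56 reference (γ, label) pairs bundled in
  `inst/extdata/effect_size_labels.csv`.
* Median with 2000-resample bootstrap percentile CI, seeded for
  reproducible tables.

## The synthetic test bed

`generate_ppg()` builds PPG with known ground truth: instantaneous heart
frequency `f_h(t) = f_heart(1 + a_rifv sin 2π f_resp t)` integrated to a
beat phase whose integer crossings are beat times; an asymmetric two-lobe
beat template (sharp systolic Gaussian, width 0.08 s; broader diastolic
lobe, width 0.25 s, relative height 0.4, offset +0.25 s) placed at each
beat; the train multiplied by `1 + a_riav sin(2π f_resp t + φ_a)`; baseline
`a_riiv sin(2π f_resp t + φ_i)` added; white Gaussian noise at a stated SNR
relative to the pulse train RMS. Defaults mirror a camera acquisition: PPG
at 25 Hz, respiratory reference at 1000 Hz, HR 72 beats/min, RR 15
breaths/min. Study-condition depths used throughout the tests are
`a_riiv = a_riav = 0.3` and `a_rifv = 0.05` — moderate, physiologically
plausible modulation with RSA the weakest mechanism, as in adults at rest —
at 10 dB SNR.

`generate_corrupted_respiration()` produces QC-failing references: breath
intervals mix Gaussian irregularity (floored at 0.6 of the breath period —
faster cycles are not resolvable breathing) with occasional apneic pauses
(probability 0.25 per breath), the two components calibrated so the total
interval SD equals `jitter_s`; per-cycle trough-depth perturbations with SD
`trough_noise` drive σ₂. Each breath is an in-band raised-cosine bump, so
the injected timing dispersion survives the screening band-pass — a flat
pause between bumps is exactly what the height floor in the QC detector is
for.

**What the simulator does not emulate:** real rPPG morphology (dicrotic
notch physiology), motion artifacts beyond additive white noise, drifting
respiratory rates within a window, and the coupling of the three mechanisms
through common autonomic drive. Two consequences matter when reading test
results. First, parameter-recovery tests show the estimators are *correct*,
not that they are *robust to real video artifacts*. Second, after the
0.18–1.0 Hz pre-filter the simulator's respiratory baseline is nearly a
pure tone, which flatters the decomposition methods (EMD/SSA) relative to
their behaviour on real data, where respiratory energy wanders across IMFs
and EOFs (mode mixing).

## Numerical choices and degenerate inputs

* Splines are R's `splinefun(method = "fmm")` cubics throughout.
* All-zero or constant windows: segmentation flags "no pulses"; the
  spectral picker returns `NA` when the in-band power is identically zero;
  pipeline rows degrade to `NA` and are excluded downstream, never fatal.
* Friedman on fully tied data (0/0 tie correction) is defined as statistic
  0, p = 1.
* Ties in the prominence screen resolve by removing the smallest excursion
  first; equal-value merged extrema keep the earlier point.
* Sub-sample refinement is clamped to ±half a stride and reverted for any
  pair of extrema it would make touch or cross.
* Problem sizes in the test suite (100 windows of ~100 samples for
  reconstruction identities, 80 s recordings for recovery grids, 200
  replicates for the Friedman null) were chosen to exercise each property
  at comfortable statistical resolution while keeping the default suite
  around half a minute.

## Known limitations

* The IMS pre-filter band and the adaptive-band rule `[0.1, min(0.6, HR/2)]`
  are package design choices (exposed as configuration); different
  reasonable choices shift individual estimators by up to a few
  breaths/min on noisy data.
* RR below 6 breaths/min (0.1 Hz) is outside every search band and will not
  be detected.
* The per-video aggregation (median over windows) assumes RR is roughly
  stationary within a recording.
* `RR_EOF3` and `RR_IMF1` often track cardiac rather than respiratory
  content; they are reported because the comparison framework is the point,
  not because they are recommended estimators.
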