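---
title: "Methods: estimating and using the sleep EEG envelope spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and using the sleep EEG envelope spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepenv)
```

## The quantity being estimated

The ordinary sleep EEG spectrum describes which frequencies make up the
signal. The *envelope spectrum* describes something different: how the
instantaneous amplitude of band-limited activity waxes and wanes over
time. If sleep spindles (sigma-band activity) recur every four seconds,
the sigma envelope oscillates at 0.25 Hz, and the spectrum of that
envelope shows a 0.25 Hz peak even though the signal itself contains no
0.25 Hz component.

The estimation chain implemented here is:

1. filter each channel into a frequency band,
2. take the modulus of the analytic (Hilbert-transformed) signal as the
   instantaneous amplitude,
3. estimate the power spectral density of that envelope from long
   windows placed over artifact-free, single-vigilance-state data,
4. smooth, log-transform and z-score the result.

Downstream of the estimate sit three analyses: coupling of the envelope
to a neuronal-firing proxy with surrogate-based inference, within-night
reliability, and multivariate phenotype prediction.

## Band filtering and the envelope

Eight canonical bands are used (`canonical_bands()`): low delta
0.5–2 Hz, high delta 2–4, theta 4–7, alpha 7–10, low sigma 10–12.5,
high sigma 12.5–16, beta 16–30 and gamma 30–49 Hz. Filtering is
zero-phase: a linear-phase least-squares FIR design (`firls_design()`,
the same closed-form normal-equation design as MATLAB/scipy `firls`)
applied forward and backward, i.e. the signal's spectrum is multiplied
by the squared magnitude response. Transition bands extend 15% of each
edge frequency beyond the pass-band.

The filter order matters more than is often appreciated. A popular
heuristic uses three cycles of the lowest pass-band frequency, but at
that length the design cannot realize the 15% transitions of the narrow
low-frequency bands, and the squared (two-pass) response then droops by
up to 10% inside the pass-band and leaks around the edges. The default
here is nine cycles (`9 * rate / low_edge` taps): a length-`N` FIR
resolves transitions of roughly `3.3 * rate / N` Hz, which keeps the
two-pass pass-band flat to about 1–4% across all eight bands while
attenuating out-of-band tones by more than 60 dB. The order remains a
user-visible argument for anyone wanting the shorter classical filters.

The envelope is computed once on the continuously filtered recording
(not per window), so window boundaries introduce no filtering
transients; windows are then cut out of the continuous envelope. No
padding is applied around the Hilbert transform; the few samples of
edge bias at the very start and end of a recording are negligible at
the window lengths used and are shared by all windows equally.

## Colliding-window PSD estimation

Very low envelope frequencies require long spectral windows — here
100 s, stepped every 20 s (80 s overlap) — which makes artifact handling
the central design problem: discarding a whole 100-s window because of
one 4-s artifact would waste up to 96 s of clean signal per artifact.

The colliding-window rule (`plan_windows()`) instead shortens a window
that would run into an obstruction — an artifact cell (4-s grid) or a
vigilance-state boundary (20-s grid) — so that it ends exactly at the
obstruction, down to a minimum of 20 s; shorter candidates are dropped.
Full-length placement resumes at the next clean in-state point of the
20-s candidate grid after the obstruction. Because this still leaves
the stretch just after an obstruction under-sampled, the same rule is
run backward from the recording end and the two passes are pooled
(duplicate windows counted once). Around an isolated artifact the two
passes together leave at most 20 s of clean signal uncovered — the
guarantee the acceptance suite verifies by exhaustive mask lookup.

Two consequences of shortening are handled at aggregation
(`aggregate_psd()`): a window of length `L` carries weight `L/100` in
the across-window weighted mean, and its PSD bins below `1/L` Hz are
discarded (a window cannot estimate cycles longer than itself). Each
window's PSD (`window_psd()`) is computed from the linearly detrended,
Hamming-tapered envelope segment, evaluated on the fixed
0.01–4.00 Hz grid (0.01 Hz steps) by zero-padded DFT so that all
windows, whatever their length, land on the same 400 bins.

The aggregated spectrum is Savitzky–Golay smoothed (polynomial order
10), 10-base log-transformed, and z-scored across the 0.01–2 Hz
analysis sub-grid per band and channel. Choices that the procedure
leaves open, fixed here:

* **Smoothing frame: 21 bins (0.21 Hz).** The smallest odd frame
  comfortably above the polynomial order; it suppresses bin-to-bin
  estimator noise while leaving the ~0.05 and ~0.25 Hz peaks intact.
* **z-scoring range: the 0.01–2 Hz analysis sub-grid**, not the full
  4 Hz estimation grid, since envelope frequencies up to 2 Hz
  constitute the analyzed feature space.
* **Non-positive densities after smoothing** (possible overshoot next
  to steep spectral edges) are clipped to the smallest positive
  observed density before the log, with a message.
* **Missing bins inside the sub-grid** (frequencies where no window was
  long enough) are linearly interpolated before smoothing, with a
  message; a spectrum with no valid bins anywhere is an error.
* **Degenerate flat spectra** make the z-transform undefined and raise
  an error rather than returning NaNs.
* **Stage boundaries collide like artifacts**, so windows never span
  NREM/REM/wake transitions; within-NREM stage changes (N2 to N3) do
  not collide, because NREM is pooled.
* **Cohort quality screening** replaces visual inspection with a
  reproducible rule (`flag_abnormal_spectra()`): a subject is flagged
  in a band when its log-spectrum deviates from the cohort mean by
  more than 5 cohort SDs at more than 10% of bins. Flagged, never
  silently dropped.

```{r fig-demo}
rec <- make_fig_signal(sim_spec(duration = 300, seed = 1))
ann <- make_mask_and_stages(300, list(),
                            list(list(stage = "N2", start = 0, end = 300)))
eps <- suppressMessages(
  envelope_spectrum(rec, ann$mask, ann$stages, "NREM", bands = demo_bands()))
eps
```

## Coupling to neuronal firing

A firing-rate proxy (multi-unit activity) is derived from high-rate
intracortical data by rectification and a 20 Hz low-pass
(`compute_mua()`); for coupling with a band whose upper edge is `f`,
the proxy is additionally smoothed by a centered moving average of
`1/f` seconds (`smooth_mua_for_band()`), removing proxy fluctuations
faster than any possible envelope oscillation of that band.

Coupling is quantified over non-overlapping 20-s artifact-free NREM
segments by three segment-averaged statistics (`coupling_analysis()`):

* coefficient-normalized cross-correlation at lags within ±1 s;
* magnitude-squared coherence at 0.1–1.0 Hz, from 10-s Hamming
  sub-windows with 50% overlap — the shortest configuration with
  0.1 Hz native resolution (the sub-windowing is a choice the
  procedure description leaves open);
* the mean z-scored envelope amplitude in twelve 30° bins of the firing
  proxy's instantaneous phase. Phase 0 is the positive peak of the
  analytic signal's real part; bins are left-closed. Empty bins
  contribute missing values excluded from the segment average.

Inference is surrogate-based (`surrogate_p()`): each envelope segment
is re-paired with a uniformly random firing segment (with replacement;
self-pairing allowed, its probability vanishes with segment count) and
the segment-averaged statistic recomputed; 1000 such surrogates form
the null. The two-sided empirical p-value uses the +1 correction,
`(1 + #(|surrogate| >= |observed|)) / (n + 1)`, which avoids exact
zeros — a deliberate, documented difference from the uncorrected
"proportion more extreme" formulation. Per-pair statistics are cached,
so the surrogate loop is an indexing operation; results are identical
to direct recomputation.

Subject-level p-values are pooled by transforming to standard normal
deviates, averaging *without weights*, and transforming back. The
unweighted average is deliberately conservative: no subject gains
influence from having more data, and pooling cannot manufacture
significance absent in every individual. Families of pooled p-values
are then controlled by Benjamini–Hochberg FDR (`fdr_bh()`, a thin
wrapper over `stats::p.adjust`), applied per band across lags and
channels (cross-correlation), per band and channel across frequencies
(coherence), and per band and channel across phase bins.

Respiratory contamination is assessed analogously
(`respiration_coupling()`): 100-s windows with 50% overlap, per-window
coherence in the respiratory range and a Kullback–Leibler
(normalized-entropy) modulation index of envelope amplitude by
respiration phase, with window-shuffled surrogates. The entropy-based
index with 12 bins mirrors the phase-binning used for firing coupling.

## Reliability

Reliability asks whether the normalized envelope spectrum is a stable
individual trait within a night. Two schemes:

* **Even–odd**: windows are thinned to every fifth — with 100-s windows
  on a 20-s grid, thinned windows are 100 s apart, so their samples
  never overlap — and the thinned sequence is split by parity. The
  thinning anchor is the first window; the anchor is otherwise
  arbitrary and unstated in the procedure. Agreement across subjects
  is the intraclass correlation, implemented as a Pearson-type
  coefficient with both covariance and variance taken about the common
  (grand) mean of the two half-measurements and variances pooled. This
  grand-mean form is what makes the ICC sensitive to mean differences
  between halves (a per-series-mean form would not be), and it equals
  the one-way sums-of-squares form `(SSB - SSW)/(SSB + SSW)`, which
  the test suite verifies against a brute-force ANOVA decomposition.
* **Split-half**: first versus last 50% of windows, compared with the
  ordinary Pearson correlation, which ignores the systematic
  within-night drift in mean voltage that would depress the ICC.
  Coefficients are reported unsquared — the conservative choice.

Both halves pass through the full post-processing (smoothing, log, z),
so reliability is invariant to any global rescaling of the raw signal.

## Phenotype prediction

The feature space is the z-scored envelope PSD between 0.01 and 1 Hz
(the first 100 bins) of all eight bands — 800 predictors per channel
and state. The validation split orders subjects by the phenotype and
holds out every 8th starting from the first (stable tie-break by
subject id): for 176 subjects, 22 validation and 154 training, with the
validation sample spanning the phenotype's range.

The model is an elastic net with mixing 0.5, fit by coordinate descent
(`glmnet`) over a 100-value log-spaced penalty path down to `1e-4` of
the data-derived maximum, with the penalty chosen by minimum mean
squared error under seeded fivefold cross-validation (folds stratified
by phenotype quantile for stability). Minimum-CV-error selection, not
the 1-SE rule, because predictive accuracy is the target quantity.
Feature standardization uses training-row statistics only; the test
suite asserts the absence of validation leakage. Sex enters as a
continuous 0/1 variable, so its validation accuracy is a point-biserial
correlation. Fits that error, return non-finite coefficients, or face
a constant response are reported as non-converged with accuracy
recorded as 0 and excluded from cross-channel averages; null fits that
select the empty (intercept-only) model produce constant predictions
whose correlation is undefined and likewise drop out.

## The synthetic-data generator

Because raw recordings cannot ship with the package, every analysis is
exercised on synthetic data whose ground truth is known:

* `make_fig_signal()` builds the demonstration signal: a 2 Hz sinusoid
  whose amplitude is modulated at 0.2 Hz plus a 12 Hz sinusoid
  modulated at 1 Hz, in pink noise. The modulation law is the
  non-negative `1 - d + d(1 + sin(2*pi*f_c*t))/2` with depth `d = 1`
  and unit component amplitudes by default. Pink noise comes from
  frequency-domain shaping of seeded white Gaussian noise (exact slope
  control, bit-reproducible given a seed). The default noise SD of 0.5
  (half the component amplitude, roughly +8 dB in-band SNR in the
  delta range) keeps the carrier peaks clearly recoverable through
  sharp, contract-conforming filters while leaving a visible noise
  floor; substantially stronger noise lets the in-band 1/f noise
  envelope swamp the 0.2 Hz line.
* `make_coupled_pair()` couples a rectified-Gaussian firing proxy to
  the phase of a band-limited signal's envelope with configurable
  preferred phase, strength and lag — the ground truth for the
  coupling recovery and calibration suites.
* `make_cohort()` draws phenotypes (age uniform 17–69, sex
  Bernoulli(0.5), IQ normal 100/15) and envelope-spectrum feature
  arrays in which each declared effect locus has expected
  feature–phenotype correlation exactly equal to the declared effect —
  the ground truth for univariate FDR calibration and multivariate
  recovery, with a closed-form achievable prediction ceiling.

What the generator does *not* emulate: realistic full-night sleep
architecture, cardiac or movement artifacts, volume conduction and
channel correlation structure, or the empirical shape of real envelope
spectra (cohort features are independent noise outside effect loci).
Passing tests therefore demonstrate correctness and calibration of the
estimators — not that real sleep EEG meets the statistical assumptions.
In particular the cohort-level reliability and prediction magnitudes
reported for real data cannot be reproduced from synthetic inputs and
are not asserted anywhere.

## Problem sizes and determinism

The test and acceptance suites run on deliberately modest problem
sizes, chosen as the smallest at which each property is
distinguishable from its failure mode: 300–600 s single-channel
recordings at 100–250 Hz, cohorts of 176 subjects (2000 where a
convergence claim is tested), 200-surrogate nulls across 200
replicates for type-I calibration, 50 seeded cohorts for the
prediction null. All randomness flows through explicit integer seeds;
the same seed yields bit-identical synthetic data and surrogate
pairings across runs.

## Known limitations

* EDF input is not implemented; signals enter as CSV matrices with a
  JSON side-car (or programmatically as `recording()` objects).
* The Hilbert envelope is biased at the extreme recording edges (no
  padding); with 100-s windows this affects a vanishing fraction of
  samples.
* The coherence estimator's small-sample bias floor (three sub-windows
  per 20-s segment) is substantial; inference is therefore always
  surrogate-based rather than parametric.
* `surrogate_p()` caches all evaluated pairs; for very large segment
  counts with vector statistics this trades memory for time.
* The abnormal-spectrum flag is a reproducible stand-in for visual
  quality control, not a validated artifact detector.
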