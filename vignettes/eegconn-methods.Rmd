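---
title: "Quantitative EEG band power and directed connectivity: models and methods"
author: "eegconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG band power and directed connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific setting

Patients with prolonged disorders of consciousness (vegetative or minimally
conscious states persisting beyond 28 days) show characteristic changes in
resting EEG: background slowing (power shifting from the alpha band into
delta), loss of the frontal power predominance of healthy wakefulness, and
weakened directed interactions between brain regions, particularly across
hemispheres. `eegconn` implements the quantitative-EEG workflow used to
quantify these changes and to test how well each index separates a patient
cohort from healthy controls:

1. preprocessing of multichannel scalp recordings,
2. Welch band/region power ratios and DTABR,
3. three connectivity estimators -- band-limited Pearson correlation,
   pairwise Granger causality, and phase transfer entropy (PTE),
4. nonparametric group statistics (Mann-Whitney U, ROC/AUC),
5. a synthetic cohort generator with known ground truth, used by the test
   suite to verify that every step recovers what it is supposed to recover.

The pipeline operates at sensor level on 10-20-system channels. Source
localization, head modelling and cortical parcellation are out of scope;
precomputed parcel time series can be analyzed through the same
matrix-format input path. Component-based artifact removal (ICA) is also
out of scope: a deterministic amplitude screen stands in for it (below).

## Preprocessing

`preprocessRecording()` applies a second-order IIR notch (default 50 Hz,
quality factor 30) followed by a fourth-order Butterworth band-pass
(default 0.5-40 Hz). Both filters run forward-backward (`filtfilt`), so
the chain is zero-phase. This matters because PTE operates on
instantaneous phases: any group delay introduced by one-pass filtering
would bias phase relations between channels. The trade-off (doubled
effective filter order, edge transients at the recording boundaries) is
acceptable for recordings of a minute or more.

`epochAndReject()` cuts consecutive non-overlapping epochs (default 2 s)
and drops any epoch whose peak absolute amplitude exceeds a limit
(default 100 uV) on any channel. This is a deliberately simple, fully
deterministic artifact screen: on real data it removes gross movement and
electrode artifacts, while ocular/cardiac component removal is left to
external tooling before import. Epoch length and limit are configuration
keys (`epoch_length_s`, `amplitude_limit_uv`); neither has a canonical
published value, so the defaults are package choices.

## Spectral power, ratios, DTABR

`welchPsd()` estimates the one-sided power spectral density per channel by
Welch's method: Hann-windowed, constant-detrended segments (default 2 s,
50% overlap) within each kept epoch, averaged across all segments. The
density normalization satisfies Parseval: the trapezoidal integral of the
PSD over the frequency grid approximates the signal variance. The
implementation reproduces the reference `scipy.signal.welch` output to
floating-point accuracy for identical parameters (checked in the test
suite).

`summarizePower()` uses the classical clinical bands delta 1-3, theta 4-7,
alpha 8-13, beta 14-30 Hz (closed intervals on the grid). Two conventions
deserve mention:

* **Band ratios** are shares of the *four-band total*, not of the full
  0.5-40 Hz integral. Published group percentages for these four bands sum
  to ~100%, which is only possible if the gap frequencies (3-4, 7-8,
  13-14 Hz) are excluded from the denominator; we adopt that convention.
* **Region power** sums each region's channels over the union of the four
  bands, with the montage partition frontal = {Fp1, Fp2, F3, Fz, F4, F7,
  F8}, central = {C3, Cz, C4}, temporal = {T3, T4, T5, T6}, parietal =
  {P3, Pz, P4}, occipital = {O1, Oz, O2}. The T7/T8/P7/P8 montage dialect
  is accepted on input and mapped to the classical names.

DTABR = (P~delta~ + P~theta~) / (P~alpha~ + P~beta~) summarizes slowing in
one number; it is scale-invariant and strictly increasing in delta mass,
both property-tested. `cohortPowerTable()` reports per-group means of
per-subject ratios by default; a pooled mode (sum absolute powers across
subjects, then form ratios) is available because group percentages in the
literature are sometimes computed that way and the two differ when
subjects have very different total power.

## Connectivity estimators

All three estimators return a `ConnMatrix` with channel dimnames; failed
pairs are `NA`, never silently zero, so group statistics can exclude them
explicitly.

### Band-limited Pearson correlation

Per epoch, channels are zero-phase band-pass filtered and the Pearson
product-moment correlation is computed per pair, then averaged across
epochs (plain average; epochs are equally long). For narrow low-frequency
bands (delta at 2-s epochs holds at most six cycles) the per-epoch filter
transient dominates, so the `EEGRecording` method filters the continuous
recording once and epochs afterwards; the pipeline uses that path.

### Pairwise Granger causality

For each ordered pair (i, j), GC(i -> j) = ln(sigma^2_restricted /
sigma^2_full), where the restricted model predicts channel j from its own
lags and the full model adds channel i's lags. Models are least-squares
VAR fits with intercept; epochs (or artifact-free runs of the continuous
recording) are separate realizations sharing coefficients, so lagged rows
never cross epoch boundaries. The lag order is selected per pair by BIC
over 1..6 (the conventional clinical maximum); `fitVAR()` additionally
rejects orders whose companion-matrix spectral radius reaches 1. Because
restricted and full models are nested and share the sample, the RSS ratio
is >= 1 and GC >= 0 by construction; any residual negative rounding is
clipped.

Two binarization mechanisms are provided, because "a threshold on directed
connections" can mean either:

* the F-test of the restriction at level alpha (default 0.05), returned as
  the `granger_binary` matrix -- exact under white innovations, verified
  by a 500-replicate null calibration; and
* a fixed threshold on the GC value itself (`thresholdDirected()`, pipeline
  default 0.02, i.e. the source's past must reduce the target's prediction
  error by at least 2%).

The pipeline's edge counts use the fixed-value threshold. The reason is
statistical: on long recordings (tens of thousands of samples) of signals
whose innovations are not white -- which includes band-structured EEG --
the F-test detects arbitrarily small model-mismatch effects and saturates,
so edge counts based on it reflect sample size rather than coupling
strength. A fixed effect-size threshold keeps edge counts comparable
across groups and recording lengths. Bivariate (not conditional) GC is
used throughout; with chains x -> y -> z the bivariate statistic will
genuinely flag x -> z, which is the standard caveat of pairwise analysis.

### Phase transfer entropy

Within a band, the instantaneous phase of each channel is the argument of
the analytic signal of the zero-phase-filtered trace. With Yf the target
phase `delay` samples ahead,

PTE(x -> y) = H(Yp, Xp) + H(Yf, Yp) - H(Yp) - H(Yf, Yp, Xp),

estimated from binned phase histograms (natural log; diagonal 0 by
convention). Defaults:

* **delay** = half an average oscillation cycle of the band,
  `round(rate / mean(band) / 2)` samples -- long enough for phase
  information to propagate, short enough to stay within the
  autocorrelation time of the band;
* **bins** = `ceiling(sqrt(n))` capped at **16**;
* **Miller-Madow correction**: each plug-in entropy term receives the
  (K-1)/(2N) occupancy correction.

The bin cap and the Miller-Madow correction address the dominant
finite-sample failure mode of histogram transfer entropy: with b bins the
three-dimensional histogram has b^3 cells, and for b near sqrt(N) the
plug-in estimator overfits, producing a positive bias that *depends on the
in-band signal-to-noise ratio* of each channel. In a group comparison
where the groups differ spectrally by design, that bias difference can
exceed and even reverse the true coupling difference. Capping at 16 bins
(4096 cells) and correcting first-order occupancy bias keeps the
estimator's bias small relative to real phase-coupling effects. For the
same reason the pipeline computes PTE on contiguous artifact-free runs of
the continuous recording (length-weighted average across runs) rather than
on 2-s epochs: the bias scales like 1/N per segment, and a 2-s delta-band
segment is shorter than a single delay at the default settings. The
per-epoch interface remains available on `EpochSet` inputs for short,
clean segments at higher frequencies.

Directionality is validated against delayed phase-coupled oscillator
pairs (below) and against circular-shift surrogates, which destroy
coupling while preserving each channel's phase dynamics.

## Group statistics

`mannWhitney()` computes U from midranks. Exact mode enumerates all
`choose(n1 + n2, n1)` group assignments of the observed (possibly tied)
ranks and returns p = min(1, 2 min(P(U <= u), P(U >= u))); it is verified
against an independent pairwise-counting enumeration on random small
samples. Normal mode uses the tie-corrected variance with a 0.5 continuity
correction; it matches `wilcox.test(exact = FALSE, correct = TRUE)` to
machine precision. `rocAuc()` sweeps unique scores, integrates by
trapezoid (so AUC = U / (n1 n2) exactly, ties included) and attaches a
Hanley-McNeil 95% interval -- an adequate closed form at cohort sizes
where the bootstrap would dominate runtime; DeLong intervals are a
non-goal.

`contrastConnectivity()` compares one metric/band between cohorts. The
default pooling, `per_edge_pooled`, pools all finite off-diagonal values
(upper triangle for undirected metrics) across subjects per group. This is
the convention that produces the very large |Z| values familiar from
edge-level EEG reports, and it treats dependent edges of one subject as
independent observations -- a documented caveat, which is why
`per_subject_mean` (one mean value per subject; valid but far less
powerful) is offered alongside. No multiple-testing correction is applied
across bands/metrics by default, matching common reporting practice;
`p.adjust` can be applied to the result table by the user.

## The synthetic cohort generator

Because clinical EEG of this population is not publicly deposited, the
package ships a generator whose defaults *are* the study conditions used
by the test suite, with every generative element recoverable by an
analysis step:

| element | cg_like (control) | doc_like (patient) | recovered by |
|---|---|---|---|
| band profile (delta, theta, alpha, beta) | 0.21, 0.11, 0.55, 0.13 | 0.56, 0.27, 0.15, 0.02 | band ratios, DTABR |
| region gain | frontal x1.8 | frontal x0.5, occipital x6 | region ratios |
| directed edges | 24 edges, strength 0.45, lags 4-9, incl. 6 cross-hemisphere; flow centred on central/parietal channels | 5 edges, strength 0.2, lags 6-8, all toward temporal channels, none cross-hemisphere | GC edge counts, hemisphere partition |
| shared alpha source gain | 0.8 | 0.2 | Pearson |
| white noise SD | 0.3 | 0.3 | -- |

Each channel's innovation is a sum of unit-variance band-limited noise
components weighted by sqrt(region/band weight), plus the shared
alpha-band source, plus white noise; the directed graph then acts as a
structural VAR (target channels receive lagged copies of source
channels), whose companion spectral radius is checked at construction.
Band profiles follow the published group percentages in direction; the
region gains emulate the frontal-dominance reversal and occipital share
inflation qualitatively, not numerically. Cohort defaults are 9 controls
and 11 patients -- the study's sizes -- at 250 Hz (a deliberate
downsampling of clinical 2 kHz acquisition that leaves all bands below
31 Hz unaffected) for 120 s per subject, which keeps the full pipeline
within minutes on one CPU. Subject heterogeneity is multiplicative
+/- 10% jitter on the weight matrix, drawn deterministically from the
master seed before any simulation so cohorts are order-independent.
The amplitude scale (mean channel RMS 8 uV) is calibrated so that these
artifact-free recordings pass the 100 uV screen even on the hottest
occipital patient channels (~5 sigma of headroom), as artifact-free awake
EEG should; a generator whose signals routinely trip its own pipeline's
artifact screen would fragment the analysis segments and confound the
phase metrics with short-segment bias.

`simulatePhaseCoupledPair()` provides the targeted PTE validation: two
noisy phase oscillators at the band centre where the receiver's phase
increment pulls toward the driver's phase from `delay` samples earlier
(strength `kappa` in units of the angular step). `kappa = 0` gives
exactly independent oscillators for null checks.

What the generator does *not* emulate -- and hence what passing tests do
not establish about real data: volume conduction and reference effects
(zero-lag mixing that inflates sensor-level Pearson r), real artifacts
(ocular, cardiac, movement), nonstationarity over minutes, 1/f background
structure, and individual anatomy. Sensor-level conclusions on clinical
data need source-space or leakage-robust confirmation; this package's
claim is that the *estimators and statistics* behave correctly, not that
sensor-level EEG is leakage-free.

## Numerical choices and degenerate inputs

* Filters: Butterworth order 4 band-pass, biquad notch Q = 30, both via
  `filtfilt`; the delta band at 250 Hz (normalized edges 0.008-0.024) was
  verified stable under the doubled effective order.
* Welch: periodic Hann window, per-segment constant detrend, one-sided
  scaling with the DC and Nyquist bins not doubled.
* Band integrals: trapezoid on the closed band interval of the grid; a
  boundary grid point belongs to the lower band (moot for the default
  integer bands with gaps).
* All-zero spectra yield a flagged degenerate summary rather than 0/0.
* Zero-variance or constant channels raise named errors
  (`degenerate-channel error: ... C4`) instead of propagating NaN.
* Duplicated channels make a VAR pair's design singular; `grangerPairwise`
  records the pair as failed and continues.
* Exact Mann-Whitney refuses n1 + n2 > 20 (enumeration size); auto mode
  switches to the normal approximation there.
* Determinism: every simulation takes an explicit seed; per-subject seeds
  derive from the master seed before generation; pipeline tables are
  written with fixed `%.15g` formatting so identical configurations
  produce byte-identical output.

## Problem sizes used by the test suite

Module tests run on seconds-long recordings. The statistical guarantees
are tested at the sizes the methods are meant for: exact-test enumeration
against brute force on 200 random small samples; F-test and Mann-Whitney
null calibration on 500 replicates each against the exact binomial 99%
band; directed-coupling recovery on 100 seeds (binary GC on a single
lagged edge of strength 0.7 over 5000 samples; PTE on delayed
phase-coupled pairs at kappa = 1); and the full pipeline on the default
9 + 11 cohort at 120 s per subject. These sizes were chosen as the
smallest at which the respective asymptotics are comfortably in force.

## Known limitations

* Bivariate GC conflates direct and indirect influence; conditional
  multivariate GC is out of scope.
* Sensor-level Pearson r is inflated by volume conduction on real data;
  the generator reproduces shared-source coupling but not realistic
  leakage geometry.
* Edge-pooled Mann-Whitney Z values overstate evidence because edges
  within a subject are dependent; use `per_subject_mean` when calibrated
  inference matters more than comparability with edge-pooled literature.
* Histogram PTE remains biased at very short segments even with the
  Miller-Madow correction; prefer continuous runs of at least ~30 s for
  delta-band PTE at 250 Hz.
* The EDF writer targets plain 16-bit EDF with one-second records and
  integer sampling rates; EDF+ annotations are not written.
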