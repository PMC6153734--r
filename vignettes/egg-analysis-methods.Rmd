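---
title: "Methods: gastric slow-wave spectral analysis with eggwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gastric slow-wave spectral analysis with eggwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggwave)
```

## The measurement problem

The cutaneous electrogastrogram records the gastric slow wave — the
pacemaker rhythm of the stomach, near 3 cycles per minute (cpm) — through
abdominal surface electrodes. The signal of interest occupies 0.5–9 cpm
(0.008–0.15 Hz) at 50–400 µV, superimposed on respiration, the ECG, colonic
activity and movement artifacts that are orders of magnitude larger. All
clinically used EGG parameters are therefore spectral: the examination is
segmented, a power spectral density (PSD) is estimated per segment, and the
location and height of the dominant peak in 0.5–9 cpm — the dominant
frequency (DF) and dominant power (DP) — feed every downstream statistic.

`eggwave` implements that pipeline end to end for up to four EGG channels
plus one auxiliary sensor channel, with a running (per-segment) and an
overall (averaged-spectrum) analysis, the standard clinical parameter set,
an optional HRV sub-pipeline, and a synthetic-signal generator that
reproduces the validation conditions.

## Pipeline and assumptions

1. **Downsampling first.** Recordings above 4 Hz are zero-phase low-pass
   filtered (4th-order Butterworth, cut-off 2.0 Hz) and decimated to 4 Hz;
   integer factors decimate directly, non-integer factors (e.g. 250 Hz) go
   through polyphase rational resampling. We downsample *before* band
   extraction: at 200–250 Hz the band edges 0.008/0.15 Hz are so far below
   Nyquist that IIR band-pass designs become numerically ill-conditioned,
   while at 4 Hz the same design is well behaved (largest pole modulus
   0.996). Both steps are linear, so the order does not change the ideal
   result; it only changes conditioning.
2. **Band extraction.** Three zero-phase options, all applied only to EGG
   channels (the sensor channel passes through):
   * `butterworth` — a 4th-order Butterworth band-pass applied
     forward-and-reverse (`filtfilt`). "4th order" follows the MATLAB
     band-pass convention (design order 4, polynomial order 8), which is
     what clinical EGG software built on MATLAB produces.
   * `zero_phase_inverse_butterworth` — the band-stop complement: the
     band-stop-filtered signal (same design order, forward-and-reverse) is
     subtracted from the input. This realizes a differently shaped pass
     band under the same zero-phase guarantee.
   * `ib_dct` — whole-signal DCT masking: coefficients of the even-symmetric
     cosine transform whose frequencies $f_k = k f_s / (2N)$ fall outside
     the pass band are zeroed and the transform inverted. Implemented via
     the even-extension FFT identity, which is exact and $O(N\log N)$.
3. **Artifact rejection.** Both detectors tile the band-passed signal into
   analysis-length segments, compute the sample SD per tile, and set the
   limit $L = \theta\,\overline{s}$. Method 1 ($\theta$ default 4.2) flags
   a tile when any sample magnitude exceeds $L$; Method 2 ($\theta$ default
   1.6) when the tile SD exceeds $L$. Comparisons are strict (`>`), which
   makes the all-zero signal well defined (no flags). Detection runs per
   channel; the combined mask is the OR across channels plus any manual
   minute-intervals, and an excluded tile is excluded for *all* channels.
   The SD statistics are computed on the extracted EGG (detection follows
   extraction in the workflow); the tile length defaults to the RSA segment
   length so exclusions align with analysis segments. Manual intervals use
   closed-interval overlap: an exclusion that touches a tile boundary flags
   both neighbouring tiles (conservative in the clinical direction).

## Spectral estimation

* **Grids.** All estimators evaluate one-sided spectra on `lspv` points
  (default 4096) over $[0, f_s/2)$; at 4 Hz the grid step is
  $f_s/(2\,\mathrm{lspv}) = 4.883\cdot10^{-4}$ Hz = 0.0293 cpm. Frequencies
  are reported in cpm and densities in mV²/cpm.
* **Periodograms.** The demeaned segment is tapered (Tukey $\alpha=0.25$
  default; Bartlett-Hann and Hann alternatives), zero-padded to twice
  `lspv` and transformed; scaling by $1/(f_s \sum w^2)$ makes the mean
  level of unit-variance white noise independent of the window. The window
  functions are generated in-package from their closed forms.
* **Burg AR spectra.** The segment is tapered, an AR model is fitted by
  Burg's method, and the order is the AIC minimum over candidate orders
  1–30 **plus 6** — the constant increase sharpens spectral detail for
  short gastric segments. Degenerate (constant) segments fall back to
  order 1 + 6. The spectrum
  $\sigma^2 / (f_s\,|1-\sum_j a_j e^{-2\pi i f j/f_s}|^2)$ is evaluated on
  the same grid; the taper's power loss is compensated so AR and
  periodogram levels are comparable.
* **Dominant peak and the 2.5 dB rule.** The DF is the global PSD maximum
  if it lies in 0.5–9 cpm. If the global maximum sits below 0.5 cpm (DC
  leakage region), the largest strict local maximum above a 0.25 cpm DC
  guard and inside the range is examined: it becomes the (corrected) DF
  only when its height is within 2.5 dB of the global maximum; otherwise
  the segment is arrhythmic and carries no DF/DP. Ties at the maximum
  resolve to the lower frequency (`which.max`), for determinism. The DP
  reference is 1 mV²/cpm; only dB differences enter any decision, so the
  reference is a display convention.

## Overall analysis and the period plan

The examination splits into a pre-prandial period $[0, t_{meal,0})$, the
meal, and consecutive 30-minute postprandial periods (a trailing fragment
is kept when it still holds one OSA segment; meal times 0/0 mean a single
all-spanning period). Segment grids restart at each period start. OSA
methods: `periodogram4` and `ar4` use 240 s segments with 120 s overlap,
`ar1` uses 60 s segments with 10 s overlap. Per period the linear segment
PSDs are averaged pointwise and the ODF/ODP and band-power distribution
(trapezoidal integration of the bradygastria $[0.5, 2)$, normogastria
$[2, 4]$ and tachygastria $(4, 9]$ cpm bands, normalized to the 0.5–9 cpm
total) are read off the averaged spectrum. The meal period is excluded
from averaging and from the whole-examination spectrum by default
(chewing and movement make it uninterpretable; `include_meal = TRUE`
overrides), and the "whole" examination is the average over all non-meal
segment PSDs.

## Clinical parameters

Per channel, per period and for the whole examination: mean/median/SD of
DF (cpm) and DP (dB) over included non-arrhythmic segments; rhythm-class
percentages over all included segments (arrhythmic segments count in the
percentages but not in DF/DP statistics, since they carry no DF);
instability coefficients as coefficients of variation — FIC on the DF
series, PIC on the *linear* dominant power by default, because the CV of
dB values is not invariant to rescaling (a `"db"` option exists for
comparability with systems that use the dB series); maximum DF difference;
slow-wave coupling between every channel pair — the percentage of segment
pairs (both DFs present) agreeing within 0.2 cpm, the convention of the
clinical literature, configurable; spatial DP difference (max minus min
per-channel mean DP); and the fed/fast power ratio
$10^{(ODP_{post}-ODP_{pre})/10}$ per postprandial period. Sample SDs use
$n-1$; a single segment has SD 0 by convention.

## HRV sub-pipeline

For recordings at $\ge$ 100 Hz (nominally 250 Hz; a warning is issued
below that): Pan-Tompkins detection (zero-phase 5–15 Hz band-pass,
five-point derivative, squaring, 150 ms moving-window integration,
adaptive dual thresholds with a 200 ms refractory period and RR-gap
search-back at half threshold; peak times refined on the zero-phase
band-passed trace). The RR tachogram (each interval at its later R time)
is resampled to 4 Hz by a natural cubic spline. Time-domain indices follow
the literal formulas (RMSSD as the root mean square of successive
differences; pNN50 with the *total number of RR intervals* in the
denominator; heart-rate statistics on the instantaneous 60000/RR series).
Frequency-domain indices use a Welch-style estimator — 256 s windows,
128 s overlap, linear detrend and Hann taper per window — integrating VLF
0.003–0.04, LF 0.04–0.15 and HF 0.15–0.40 Hz, with relative powers
referred to VLF+LF+HF and summary values as means over windows. No
ectopic-beat correction is applied before the indices; the generator-based
tests use clean synthetic ECG, so this choice is untested against real
arrhythmic data.

## The synthetic generator: what it does and does not emulate

`synth_egg_recording()` reproduces the validation conditions: per channel
$A\sin(2\pi (f_{cpm}/60) t + \varphi) + \varepsilon$ with white Gaussian
noise scaled to an exact power SNR, then mid-tread quantization through a
counts-per-mV scale chosen so the realized span uses at most 90% of the
ADC range (so quantization never clips; a user-supplied scale that would
clip raises an error stating the admissible scale). Defaults: 90 min,
200 Hz, 12 bit, 4 channels, identical phases (perfect coupling). A pink
noise option and per-channel phases exist for robustness experiments;
`inject_artifacts()` multiplies named intervals to emulate motion bursts,
and `synth_ecg_recording()` repeats a raised-cosine QRS with
sinusoidally modulated RR and returns ground-truth R times snapped to the
sample grid.

What the model deliberately omits: slow-wave propagation and phase lag
between electrode sites, frequency drift and power modulation across the
meal, respiratory and colonic interference with realistic spectra, and
electrode-contact artifacts. Passing the validation suite therefore shows
that the *estimators and rules* are correct under the stated signal model;
it does not certify performance on real recordings, where coupling
percentages far below 100% and rhythm transitions are the norm.

## Numerical choices and degenerate inputs

* Header rows are matched by position; keyword prefixes ("start:", "Fs=",
  "1mV=") are tolerated, and the value of a keyword row is the first
  number after the separator — the "1" in "1mV" is part of the keyword.
  The decimal separator is always ".", independent of locale.
* Counts are integers only at the file boundary; everything internal is mV
  (double). Round trips are bit-exact on counts and header numbers.
* Recordings with fewer than 4 EGG columns replicate channel A1 into the
  missing channels at read time, so downstream code always sees 4 channels.
* A spectrum that is identically zero yields an arrhythmic segment rather
  than an error; an all-excluded period is flagged not-computable and
  reported as NA throughout.
* Problem sizes in the test suite: unit tests run on 4 Hz records of
  1.5–75 minutes; the full-scale validation block analyzes the sixteen
  90-minute 200 Hz records exactly as specified, which dominates the
  suite's runtime (about one minute of its total).

## Known limitations

* The MUSIC overall-spectrum option of some clinical packages is not
  implemented; OSA offers `periodogram4`, `ar4` and `ar1`.
* Exports cover CSV, JSON and plain text; proprietary formats
  (MAT/Excel/Polygram) are out of scope.
* The HRV path assumes a reasonably clean ECG; there is no ectopic or
  missed-beat interpolation.
* Slow-wave propagation delay between channels (time-shift analysis) is
  not computed; coupling is frequency-agreement only.
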