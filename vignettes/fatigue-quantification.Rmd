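---
title: "Quantifying muscle fatigue from sEMG high-frequency components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle fatigue from sEMG high-frequency components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgfatigue)
```

## The problem

During repeated loaded contractions, metabolic by-products slow muscle-fiber
conduction velocity, which compresses the surface-EMG spectrum toward lower
frequencies. The median frequency (MF) of the spectrum therefore declines
roughly linearly over a fatiguing session, and the *rate* and *extent* of
that decline carry information about how fatigued the muscle is — not merely
whether it is fatigued. `semgfatigue` turns this observation into a
continuous, per-subject-calibrated fatigue level LF ∈ [0, 1].

MF is preferred here over the mean power frequency because it is less
sensitive to additive noise while remaining strongly fatigue-dependent. The
analysis runs on the highest-frequency intrinsic mode function (IMF1) of the
signal rather than the raw sEMG: the high-frequency component both drifts
more reliably and, having a lower-magnitude slope with tighter session-to-
session spread, gives a more sensitive and stable per-subject range.

## Pipeline and model

Stage by stage, for a single-channel recording at 2 kHz:

1. **Conditioning.** 4th-order Butterworth band-pass 10–400 Hz plus a
   second-order IIR notch at 50 Hz with quality factor Q = 30. Both are
   applied forward–backward, so the cascade is zero-phase and MF window
   times stay aligned with the recording. The filter family, order and
   zero-phase choice are community-standard sEMG conditioning; the
   conditioning contract itself (band edges, notch) is fixed by the
   acquisition protocol being emulated.

2. **EEMD.** Plain EMD sifts a signal into intrinsic mode functions using
   natural cubic spline envelopes through the local extrema; EEMD
   (`eemd()`) averages the EMD of many white-noise-perturbed copies
   (`noise_ratio` × signal SD, default 0.2; `ensemble_size` default 100) so
   that mode mixing cancels. Realization *m* draws its noise from seed
   `seed + m − 1`, so enlarging the ensemble refines rather than reshuffles
   the average, and parallel and serial execution would agree.

3. **Windowed MF.** IMF1 is segmented into 10,240 ms windows advancing by
   2,560 ms. The long window buys ~0.1 Hz frequency resolution (important
   because session drifts are only ~10 Hz total); the step gives a fatigue
   track point every 2.56 s. Each window yields a Hann-tapered, mean-
   detrended periodogram, and MF solves the half-energy equation on it with
   linear interpolation inside the straddling bin, so MF is not quantized
   to the bin grid. Trailing samples that do not fill a window are dropped
   rather than padded — padding would bias the terminal MF that anchors the
   calibration below.

4. **Linear fit.** Ordinary least squares of MF on window time, `y = A x + b`.
   The intercept `b` is the initial median frequency mf₀; the fitted value
   at the *last window centre* is the terminal median frequency mf_S (using
   the fitted endpoint rather than the last raw MF sample makes mf_S robust
   to single-window noise). R is reported as the absolute Pearson
   correlation: the fit quality of a *declining* line is the meaningful
   quantity, so the sign is dropped.

5. **SMFDR calibration.** For one subject and one load, the means of mf₀
   and mf_S over the training sessions define the standardized MF
   distribution range [MF̄₀, MF̄ₛ]. Calibration is never pooled across
   subjects: fiber composition, fitness and neuromuscular control make the
   absolute MF range individual. A model with MF̄₀ ≤ MF̄ₛ has no downward
   fatigue range; it is flagged and the estimator refuses it.

6. **N-level quantizer.** The range is divided into N levels of width
   Δ = (MF̄₀ − MF̄ₛ)/(N − 1). Interval k (k = 0…N−1) is
   (MF̄₀ − (2k+1)Δ/2, MF̄₀ − (2k−1)Δ/2], centred on MF̄₀ − kΔ, and the
   reported level is LF = k/(N − 1). The centre of the first interval is
   exactly MF̄₀ (LF = 0) and of the last exactly MF̄ₛ (LF = 1), which is
   what makes Δ use N − 1 rather than N.

### Design choices in the quantizer

Three points in the level rule were genuinely open and are fixed as package
policy:

* **Discrete index vs. continuous LF.** The interval formula treats the
  level as the integer index k; the user-facing LF is k/(N − 1) so that the
  scale always spans [0, 1] regardless of N.
* **Out-of-range clamps.** A fitted MF *above* the calibrated range means
  the muscle is fresher than its calibration, so it clamps to k = 0; *below*
  the range clamps to k = N − 1 (fully fatigued). This is the only
  orientation consistent with MF declining under fatigue and with the
  trajectory being monotone for a negative slope. The opposite convention
  is available as `out_of_range = "inverted"` purely for auditing.
* **Boundary ties.** A value exactly on an interval edge belongs to the
  lower-frequency (more fatigued) interval — intervals are half-open
  (lo, hi] — making the quantizer deterministic and monotone.

`N = 3` (non-fatigued / transitional / fatigued) is the default: finer
grids subdivide the range by less than the between-session spread of mf₀
and mf_S, so level assignments near boundaries become calibration-noise
driven, while N = 2 discards the transitional state that is usually the
point of continuous monitoring.

## The synthetic generator

No subject recordings ship with the package, so `synth_emg()` provides a
ground-truthed stand-in for a recorded session: Gaussian white noise shaped
by a block-wise Butterworth band-pass whose centre frequency follows the
programmed linear MF trajectory, scaled to 0.5 mV RMS, amplitude-modulated
once per contraction cycle, plus an optional 50 Hz sinusoid and broadband
noise floor.

Defaults emulate the heavy-load study condition the estimator targets:
160 s sessions at 2000 Hz, 4 s cycles (raised-cosine burst over 75 % of the
cycle, 25 % rest), MF drifting 136 → 122 Hz (−0.0875 Hz/s), 40 Hz spectral
spread, modulation depth 0.5, 2 % noise floor. A non-fatiguing control is
`mf_end = mf_start`. The drift is realized block-wise (0.5 s blocks, 50 %
overlap-add Hann crossfade) rather than with a true time-varying filter:
at drift rates below 0.2 Hz/s the centre frequency moves by ~0.02 Hz per
block, far below the MF estimator's resolution. For a symmetric band-pass
the spectral median is its centre frequency, so the programmed `true_mf(t)`
is the ground truth against which recovery is judged; filter-rolloff
asymmetry is absorbed by the ±5 Hz tolerance used in stationary checks.

What the generator deliberately does *not* model: motor-unit recruitment
and firing statistics, amplitude growth under fatigue (only the frequency
signature is programmed), movement artifacts, and electrode noise
nonstationarity. Passing tests therefore demonstrate that the pipeline
recovers a *programmed spectral drift* under realistic amplitude
modulation and noise — not that it characterizes every property of real
fatiguing sEMG.

## Numerical choices

* **Sifting.** Envelopes are natural cubic splines through the extrema with
  two extrema mirrored beyond each end to tame boundary swings; sifting
  stops on the Cauchy criterion SD < 0.2 or after 50 sifts; extraction
  stops when the residue has fewer than three extrema or after
  `max_imfs = 8` components. These are standard sifting settings; the sift
  core is compiled (Rcpp) because ensemble decomposition of 320,000-sample
  sessions dominates the pipeline's cost.
* **Degenerate inputs.** A monotone trace yields zero IMFs with the input
  as residue (not an error); an all-zero analysis window raises a
  degenerate-spectrum error rather than returning a fabricated MF; a
  zero-variance MF series yields a slope-0 fit flagged `degenerate` with
  R = 0 and a warning.
* **PSD scatter.** A single Hann periodogram's bins scatter with an
  approximately exponential distribution (max/median ≈ ln n_bins ≈ 13–15
  at these window lengths); `psd(..., segments = k)` offers Welch
  sub-averaging when a low-variance spectrum matters more than resolution.
  The default stays at one frame per window, the plain short-time Fourier
  reading of the windowing scheme.
* **Parseval normalisation.** The periodogram is taper-corrected so that
  `sum(power)·Δf` equals the Hann-weighted segment power exactly; against
  the unweighted variance of a random segment it agrees only to the ~1–2 %
  sampling scatter inherent in weighting.
* **Filter padding.** Forward–backward filtering uses odd-symmetric
  extension sized to the slowest dynamics in the cascade (three periods of
  the 10 Hz band edge and three notch ring-down time constants, ~0.6 s at
  2 kHz), which is what makes the DC-rejection and edge behaviour clean;
  traces shorter than the padding are refused as too short.

## Problem sizes used in the shipped checks

The test suite exercises the full study geometry where it matters: 160 s
sessions at 2000 Hz (59 windows), drift-recovery over 20 independent seeds,
a 3-training/2-validation split with a drift-free control, 10,000 randomized
quantizer draws against a brute-force interval scan, and 1,000 randomized
linear fits against the closed-form normal equations. The end-to-end staging
runs EEMD with `ensemble_size = 16`: the ensemble size is a variance knob on
the IMF average, and 16 realizations already track the programmed drift to
within a few percent while keeping the full workflow quick; the package
default remains 100 for analysis use.

## Known limitations

* The linear MF model is the right first-order description within one
  session but cannot represent plateaus or recovery between cycles;
  nonlinear trend models are out of scope.
* Calibration requires at least one training session of the same subject
  *and* load; the SMFDR is not transferable across loads (light loads can
  produce a near-empty range, which the estimator correctly refuses).
* Only single-channel analysis is provided; multi-channel fusion and
  real-time (streaming) estimation are out of scope.
* EDF support covers continuous equal-rate recordings (the common case for
  a single sensor), not discontinuous EDF+ sessions or annotations.
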