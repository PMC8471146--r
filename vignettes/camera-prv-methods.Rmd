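---
title: "Pulse rate variability from contact and camera PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse rate variability from contact and camera PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pulse rate variability (PRV) — the beat-to-beat fluctuation of inter-pulse
intervals in a blood volume pulse (BVP) signal — carries the same autonomic
information that heart rate variability carries in the ECG: low-frequency
(LF, 0.04–0.15 Hz) interval oscillations reflect sympathetic and baroreflex
activity, high-frequency ones (HF, 0.15–0.4 Hz) track respiration-coupled
parasympathetic activity. A contact PPG (CPPG) finger sensor measures BVP
directly; remote PPG (rPPG) recovers it without contact, from the minute
pulse-synchronous color change of facial skin seen by an ordinary 30 Hz
webcam. The question this package operationalizes is a quantitative one:
*when the same beat process is observed by both channels, how closely do
camera-derived PRV indices track the contact-derived ones, and how much of
the gap can interval-level artifact correction close?*

`prvkit` implements the full chain — camera-frame chrominance analysis,
interval extraction and cleaning, spectral PRV indices, and agreement
scoring — together with a seeded simulator that plays the role of the
paired human recordings such studies use but cannot share.

## The camera front end

Each RGB frame is converted to YCbCr (ITU-R BT.601 full-range; the
convention of consumer imaging pipelines), and skin pixels are selected by
fixed channel bounds (defaults Y ≥ 40, 77 ≤ Cb ≤ 127, 133 ≤ Cr ≤ 173 — a
widely used published skin range; all configurable, since skin chroma
varies with subject and lighting). The skin pixels' Cb–Cr centroid is a
robust one-number-per-channel summary of skin color in that frame; a
seeded isotropic Gaussian "expansion" (default n = 100 draws, sd = 1
channel unit) thickens this cluster before averaging. The expansion is a
*spatial* device: one offset set is drawn per extraction and reused for
every frame, so two identical frames always produce identical chroma and a
static scene is reported as signal-free rather than masked by expansion
noise.

Blood influx raises Cr and lowers Cb, so the two per-frame chroma series
are standardized and differenced, `z(Cr) − z(Cb)`, reinforcing the pulse
while cancelling common-mode illumination drift. A centered moving average
of width `fs/0.4` samples (≈ 2.5 s) is subtracted to remove sub-0.4 Hz
respiratory baseline wander, and a zero-phase (forward–backward) order-4
Butterworth bandpass keeps the 0.5–2.0 Hz pulse band — 30–120 bpm.
Zero-phase filtering matters because everything downstream is peak
*timing*. Frames where no pixel passes the skin bounds are bridged by
linear chroma interpolation; if more than 10% of frames lack skin the
extraction aborts rather than fabricate a signal.

Face detection and ROI tracking are deliberately out of scope: the package
consumes whole frames or a caller-supplied ROI rectangle.

## From BVP to cleaned intervals

An 11 min recording is cropped by 30 s at each end (instrument settling),
leaving 10 min that are cut into overlapped 300 s windows every 30 s —
eleven segments, `(600 − 300)/30 + 1`. Each camera-channel segment is
upsampled from 30 Hz to the contact rate of 255 Hz with an interpolating
*quadratic* spline so both channels offer the same peak-timing resolution.
The spline is a C1 order-2 B-spline with interior knots at the data
midpoints (the standard knot placement for even-degree interpolation): it
passes through every sample, reproduces polynomials of degree ≤ 2 exactly,
and interpolates a 1 Hz sinusoid sampled at 30 Hz with < 0.1% amplitude
error. No R package provides an interpolating quadratic spline
(`stats::splinefun` is cubic), so the collocation system is assembled and
solved sparsely in-package.

Peaks are local maxima above zero with a 0.5 s refractory period — the
shortest interval a 2 Hz upper band edge permits. Successive peak-time
differences give the PPI series. The cleaning rule ("normalization") is:
compute each interval's z-score against the segment mean and *population*
standard deviation (computed once, from the unmodified series), and
replace every interval with |z| ≥ T = 2, in one index-order pass, by the
median of its immediate front and back neighbors — the mean when both
exist, the single neighbor at the boundaries. Short and long outliers are
treated symmetrically. A zero-variance series is returned unchanged. The
result is the NNI series. Two open choices here — per-segment rather than
whole-recording statistics, and a single rather than iterated pass — were
resolved toward the simplest behavior that is deterministic and testable;
both are exposed through `clean_config()`.

## PRV indices

Five indicators per 300 s segment: mean NN and SDNN (population SD) in the
time domain; LFnu, HFnu and LF/HF in the frequency domain. The interval
tachogram (interval vs cumulative beat time) is resampled to a uniform
4 Hz grid with the same quadratic spline, mean-removed, and its one-sided
PSD estimated by averaged modified periodograms (Hann windows of 120 s,
50% overlap): ~0.008 Hz resolution with 3–4 averages per segment, a
sensible bias–variance point for 300 s of data. Band powers are
trapezoidal integrals of the density. With VLF fixed at 0.0033–0.04 Hz
(the HRV Task Force convention) and total power defined as the
VLF + LF + HF integral,

$$\mathrm{LFnu} = 100\,\frac{LF}{\mathrm{Total} - VLF},\qquad
  \mathrm{HFnu} = 100\,\frac{HF}{\mathrm{Total} - VLF},$$

so LFnu + HFnu = 100 by construction — a property the test suite asserts
to 1e-9 on every simulated segment.

## Agreement scoring

For each subject and indicator, agreement across the eleven segments is
the mean absolute percentage error with the contact channel as reference:

$$\mathrm{MAPE} = \frac{100}{n}\sum_{i=1}^{n}\frac{|x_i - \hat x_i|}{x_i}.$$

`build_mape_table()` assembles the per-subject rows and per-indicator
column means; `improvement_delta()` differences a PPI-basis table against
an NNI-basis one, quantifying what the z-score cleaning buys. Pearson
correlations are reported in two views: pooled NNI pairs per subject
(beats paired by index after truncating to the shorter series), and
pooled per-segment indicator pairs per indicator. The package also ships,
as `published_mape_tables()`, a transcription of a published 10-subject
benchmark of exactly this design; its column means and deltas are the
fixed reference for the aggregation arithmetic in `scripts/acceptance.R`.

## The simulator

Because paired human recordings of this kind are not shareable, the
package generates its own study conditions with an integral pulse
frequency modulation (IPFM) model: beats fall at integer crossings of the
integral of

$$r(t) = \frac{\mathrm{bpm}}{60}\Bigl(1 + d_{LF}\sin 2\pi f_{LF} t
        + d_{HF}\sin 2\pi f_{HF} t\Bigr),$$

located by Newton refinement to well under 0.1 ms. Defaults describe a
resting 11 min subject: 75 bpm, LF 0.10 Hz at depth 0.05, HF 0.30 Hz at
depth 0.03 — SDNN ≈ 33 ms, an unremarkable short-term value for a healthy
adult. Each beat is rendered as a unit Gaussian bump (sd 0.12 s) on a
255 Hz contact grid and a 30 Hz camera grid, with independent white noise
(sd 0.1 of pulse amplitude) per channel; pulse morphology is deliberately
schematic because peak timing, not shape, drives every downstream
statistic. For the video path, frames carry a skin-colored patch whose Cr
and Cb are modulated by the rendered pulse (± ≤ 5 channel units) over a
static non-skin background, with per-pixel noise dithering the 8-bit
quantization.

Motion artifacts hit the camera channel only: at Poisson epochs (default
1 per minute) a single beat time is shifted by ± a fraction (default 0.2)
of its local interval, creating the short/long outlier PPI pair that
interval-level cleaning is designed to catch. Two constraints pinned these
defaults, chosen once. First, the shift must keep both perturbed intervals
above the 0.5 s peak-detection refractory period — at 75 bpm that requires
a fraction < 0.375, else the artifact becomes a *missed beat* rather than
an outlier pair. Second, rate and magnitude together set the camera
channel's contamination, and at 1/min × 0.2 the pipeline lands in the
regime such contact-vs-camera studies actually report: PPI-basis SDNN MAPE
of a few tens of percent cleaning to single digits, pooled NNI correlation
near 0.9, per-indicator correlations above 0.95 when several subjects are
pooled.

What the simulator does *not* emulate: realistic PPG waveform shape and
its rate-dependent changes, correlated (pink) sensor noise, illumination
drift, head motion and face-tracking failures, and artifact bursts that
corrupt many consecutive beats. Passing tests therefore demonstrate that
the algorithms are implemented correctly and behave as designed under
controlled conditions — not that the camera channel would reach the same
accuracy on arbitrary real-world video.

## Numerical choices and degenerate inputs

* Butterworth order 4 applied via `signal::filtfilt`; verified stable at
  the extreme normalized cutoffs the 255 Hz channel implies (0.5 Hz /
  127.5 Hz Nyquist): a 1 Hz probe passes at 0.97 amplitude, a 5 Hz probe
  at 2e-4.
* Welch fold-back doubles interior bins only (DC and Nyquist excluded);
  total integrated power tracks the tachogram variance to within 15%.
* Ties in peak pruning resolve toward the larger maximum
  (`pracma::findpeaks`); peak times are reported at sample resolution.
* Degenerate inputs fail loudly with classed conditions:
  constant chroma (`prvkit_degenerate_signal`), skinless frames
  (`prvkit_no_skin`, `prvkit_extraction_quality` above 10%), constant
  interval series (`prvkit_degenerate_spectrum`), zero-variance
  correlation inputs, too-short signals. A zero-variance PPI segment is
  the one silent case: it is returned unchanged, since no outlier is
  definable.
* All randomness — expansion offsets, artifact placement, channel and
  pixel noise — flows from explicit integer seeds, and every generator is
  bit-reproducible; reports embed the resolved configuration and seed.

## Known limitations

The adjacent short/long outlier pair produced by a shifted beat is only
partially corrected by the neighbor-median rule: when the first interval
of a pair is replaced, its back neighbor is still the untouched second
outlier, so the replacement lands between the clean and corrupted values.
This residual is inherent to the published cleaning rule, and is the main
reason cleaned camera SDNN retains a high-single-digit MAPE under
artifacts rather than returning to the noise floor. Statistics are
per-segment; a drifting baseline rate across a segment inflates SDNN for
both channels alike. The video reader accepts PNG frame directories (or
in-memory arrays); compressed video containers are out of scope, as are
face detection and tracking.

## Problem sizes used in the checks

The test suite and acceptance script run entirely on simulated data:
11 min dual recordings (one to five subjects), 360–420 s recordings for
single-segment unit checks, and 30–40 s video clips at 30 fps and
40 × 40 px for the camera front end. These sizes were chosen as the
smallest that exercise every stage at full fidelity — eleven overlapped
segments, both channel rates, all five indicators.
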