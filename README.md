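# prvkit

Pulse rate variability (PRV) analysis for paired contact and camera-based
photoplethysmography, in R.

A contact PPG (CPPG) finger sensor and a plain 30 Hz webcam can watch the
same heartbeat: the camera sees it as a minute pulse-synchronous color
change of facial skin (remote PPG, rPPG). `prvkit` implements the complete
chain needed to ask — and answer, quantitatively — how closely
camera-derived PRV indices track contact-derived ones:

* **rPPG front end** — YCbCr conversion (BT.601 full range), skin-pixel
  filtering, Cb–Cr cluster centroid with seeded random expansion,
  standardized chrominance difference `z(Cr) − z(Cb)`, respiration
  detrending, and a zero-phase 0.5–2 Hz Butterworth bandpass
  (`extract_bvp()`).
* **Interval pipeline** — 30 s head/tail cropping, overlapped 300 s / 30 s
  segmentation, quadratic-spline resampling of the 30 Hz camera channel to
  255 Hz, peak detection with a 0.5 s refractory period, PPI extraction,
  and z-score normalization to NNI: every interval with |z| ≥ 2 (population
  statistics per segment) is replaced by the median of its front and back
  neighbors (`run_ppi_pipeline()`).
* **PRV indices** — mean NN, SDNN, and from the Welch PSD of the 4 Hz
  resampled tachogram: LFnu, HFnu and LF/HF, with
  `LFnu = 100·LF/(Total − VLF)` so LFnu + HFnu = 100 (`compute_prv()`).
* **Agreement scoring** — per-subject MAPE tables
  (`MAPE = (100/n) Σ |xᵢ − x̂ᵢ|/xᵢ`, contact as reference), column means,
  PPI→NNI improvement deltas, and Pearson correlations
  (`agreement_report()`), plus a transcribed published 10-subject benchmark
  (`published_mape_tables()`).
* **Simulator** — an IPFM beat process with sinusoidal LF/HF modulation,
  rendered simultaneously at 255 Hz and 30 Hz, with camera-only motion
  artifacts, channel noise, and pulse-modulated synthetic skin video
  (`simulate_dual_recording()`, `simulate_face_frames()`).

## Worked example

Simulate one 11 min "subject", run both channels through the interval
pipeline, and score agreement:

```r
library(prvkit)

cfg <- simulation_config(duration_s = 660, seed = 7)
rec <- simulate_dual_recording(cfg)
rec$truth
#> <ground_truth> 826 beats over 660.0 s, 10 artifact(s)

ref  <- run_ppi_pipeline(rec$contact)   # 255 Hz contact channel
test <- run_ppi_pipeline(rec$camera)    # 30 Hz camera channel
length(ref)
#> [1] 11                               # eleven overlapped 300 s segments

compute_prv(ref[[1]]$nni)
#> <prv_indices> mean NN 799.8 ms | SDNN 32.6 ms | LFnu 75.7% | HFnu 24.3% | LF/HF 3.12

agreement_report(ref, test)
#> == MAPE (%) on raw intervals (PPI basis) ==
#>  subject  mean_nn  sdnn  lfnu  hfnu lf_hf
#>        1 0.005594 32.47 20.85 66.32 51.25
#> ...
#> == MAPE (%) on normalized intervals (NNI basis) ==
#>  subject mean_nn  sdnn  lfnu  hfnu lf_hf
#>        1 0.09036 10.26 6.049 19.37 20.72
#> ...
#> NNI correlation:  1=0.899  average=0.899
```

Reading the output: the ten injected camera-channel artifacts inflate the
raw-interval (PPI) errors — SDNN disagrees with the contact channel by
32% — and the z-score normalization (NNI) pulls that down to 10% while the
mean interval stays accurate to a tenth of a percent. The pooled NNI
correlation of 0.90 says the two channels see essentially the same
beat-to-beat series. (Per-indicator correlations are only informative when
several subjects are pooled; with one subject's eleven overlapped segments
there is almost no variance to correlate.)

The camera front end itself:

```r
truth  <- simulate_beats(simulation_config(duration_s = 360, mean_rate_bpm = 60,
                                           lf_depth = 0, hf_depth = 0, seed = 5))
frames <- simulate_face_frames(truth, fps = 30, size = c(40, 40), duration_s = 40)
bvp    <- extract_bvp(frames)
dominant_frequency(bvp)
#> [1] 1                                # the configured 60 bpm pulse
```

A thin command-line wrapper (`inst/scripts/prv-cli.R`) exposes the same
stages as `simulate`, `extract`, `prv` and `compare` subcommands.

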