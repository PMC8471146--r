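#' Configuration for the paired-recording simulator
#'
#' Defines one synthetic "subject": an integral pulse frequency modulation
#' (IPFM) beat process with sinusoidal LF and HF autonomic modulation,
#' observed simultaneously by a 255 Hz contact channel and a 30 Hz camera
#' channel. Defaults describe an 11 min resting recording at 75 bpm with
#' physiologic modulation depths (SDNN ~ 33 ms), sporadic motion-artifact
#' episodes on the camera channel, and moderate additive sensor noise.
#'
#' @param duration_s recording length in seconds (>= 360; default 660, i.e.
#'   11 min).
#' @param mean_rate_bpm mean pulse rate in beats per minute.
#' @param lf_freq_hz,lf_depth LF modulation frequency (0.04-0.15 Hz) and
#'   fractional depth.
#' @param hf_freq_hz,hf_depth HF modulation frequency (0.15-0.4 Hz) and
#'   fractional depth. Depths must each lie in `[0, 0.5)` and keep the
#'   instantaneous rate positive.
#' @param artifact_rate_per_min expected motion-artifact episodes per
#'   minute (camera channel).
#' @param artifact_magnitude beat-time shift of an artifact as a fraction
#'   of the local interval (< 0.5 keeps beat order).
#' @param channel_noise_sd additive white-noise sd relative to the unit
#'   pulse amplitude.
#' @param fs_contact,fs_camera channel sampling rates in Hz.
#' @param seed integer random seed; every stochastic element derives from
#'   it, so simulations are bit-reproducible.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(duration_s = 660, mean_rate_bpm = 75,
                              lf_freq_hz = 0.10, lf_depth = 0.05,
                              hf_freq_hz = 0.30, hf_depth = 0.03,
                              artifact_rate_per_min = 1,
                              artifact_magnitude = 0.2,
                              channel_noise_sd = 0.1,
                              fs_contact = 255, fs_camera = 30,
                              seed = 1L) {
  if (duration_s < 360)
    prv_error("prvkit_invalid_config", "duration_s must be at least 360 s")
  if (!(lf_freq_hz > 0.04 && lf_freq_hz < 0.15))
    prv_error("prvkit_invalid_config", "lf_freq_hz must lie in (0.04, 0.15)")
  if (!(hf_freq_hz > 0.15 && hf_freq_hz < 0.4))
    prv_error("prvkit_invalid_config", "hf_freq_hz must lie in (0.15, 0.4)")
  if (lf_depth < 0 || lf_depth >= 0.5 || hf_depth < 0 || hf_depth >= 0.5)
    prv_error("prvkit_invalid_config", "modulation depths must lie in [0, 0.5)")
  if (lf_depth + hf_depth >= 1)
    prv_error("prvkit_invalid_config", "combined depths would drive the rate to zero")
  if (artifact_magnitude < 0 || artifact_magnitude >= 0.5)
    prv_error("prvkit_invalid_config", "artifact_magnitude must lie in [0, 0.5)")
  structure(list(duration_s = duration_s, mean_rate_bpm = mean_rate_bpm,
                 lf_freq_hz = lf_freq_hz, lf_depth = lf_depth,
                 hf_freq_hz = hf_freq_hz, hf_depth = hf_depth,
                 artifact_rate_per_min = artifact_rate_per_min,
                 artifact_magnitude = artifact_magnitude,
                 channel_noise_sd = channel_noise_sd,
                 fs_contact = fs_contact, fs_camera = fs_camera,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate beat times by integral pulse frequency modulation
#'
#' The instantaneous rate is
#' \deqn{r(t) = \frac{\mathrm{bpm}}{60}\,
#'   (1 + d_{LF}\sin 2\pi f_{LF} t + d_{HF}\sin 2\pi f_{HF} t)}
#' and beats occur where the integrated rate crosses successive integers
#' (including the zero crossing at t = 0). Crossings are located to within
#' 0.1 ms by Newton refinement of a fine-grid bracket. The process is
#' deterministic given the configuration.
#'
#' @param cfg a [simulation_config()].
#' @return a `ground_truth` list with `beat_times_ms`, `true_nni_ms`,
#'   `artifact_indices` (empty here) and the generating `config`.
#' @export
simulate_beats <- function(cfg = simulation_config()) {
  r0 <- cfg$mean_rate_bpm / 60
  dL <- cfg$lf_depth; fL <- cfg$lf_freq_hz
  dH <- cfg$hf_depth; fH <- cfg$hf_freq_hz
  rate <- function(t) r0 * (1 + dL * sin(2 * pi * fL * t) + dH * sin(2 * pi * fH * t))
  Lambda <- function(t) {
    r0 * (t + dL * (1 - cos(2 * pi * fL * t)) / (2 * pi * fL) +
            dH * (1 - cos(2 * pi * fH * t)) / (2 * pi * fH))
  }
  total <- Lambda(cfg$duration_s)
  ks <- 0:floor(total)
  # initial guess by inverse interpolation on a 10 ms grid, then Newton
  grid <- seq(0, cfg$duration_s, by = 0.01)
  t <- approx(Lambda(grid), grid, ks)$y
  for (iter in 1:4) t <- t - (Lambda(t) - ks) / rate(t)
  t[1] <- 0
  beat_ms <- t * 1000
  structure(list(beat_times_ms = beat_ms,
                 true_nni_ms = diff(beat_ms),
                 artifact_indices = integer(0),
                 config = cfg),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d beats over %.1f s, %d artifact(s)\n",
              length(x$beat_times_ms),
              x$beat_times_ms[length(x$beat_times_ms)] / 1000,
              length(x$artifact_indices)))
  invisible(x)
}

#' Inject motion-artifact episodes into a beat process
#'
#' Emulates camera-channel disturbances (facial movement, expression
#' changes, lighting): at Poisson-placed epochs an individual beat time is
#' shifted by `+/- artifact_magnitude` times the local interval, which turns
#' one clean interval pair into a short/long outlier pair. Affected beat
#' indices are recorded so downstream outlier detection can be scored.
#' Seeded from `cfg$seed` (offset so the draw stream is independent of the
#' channel-noise draws).
#'
#' @param truth a `ground_truth` from [simulate_beats()].
#' @param cfg a [simulation_config()].
#' @return a `ground_truth` with perturbed `beat_times_ms` and populated
#'   `artifact_indices`; `true_nni_ms` keeps the clean intervals.
#' @export
inject_artifacts <- function(truth, cfg = truth$config) {
  if (cfg$artifact_rate_per_min <= 0) return(truth)
  bt <- truth$beat_times_ms
  n <- length(bt)
  with_seed(cfg$seed + 104729L, {
    n_art <- rpois(1, cfg$artifact_rate_per_min * cfg$duration_s / 60)
    if (n_art == 0) return(truth)
    idx <- sort(unique(sample(2:(n - 1L), min(n_art, n - 2L))))
    sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
    for (k in seq_along(idx)) {
      i <- idx[k]
      local_nni <- min(bt[i] - bt[i - 1L], bt[i + 1L] - bt[i])
      bt[i] <- bt[i] + sgn[k] * cfg$artifact_magnitude * local_nni
    }
    out <- truth
    out$beat_times_ms <- bt
    out$artifact_indices <- idx
    out
  })
}

# Evaluate thunk with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Render a beat process as a sampled BVP signal
#'
#' Superposes one Gaussian-shaped pulse per beat (a unit-amplitude bump of
#' width `pulse_width_s`) on a uniform sample grid and adds white noise.
#' Peak timing, not pulse morphology, drives every downstream statistic, so
#' a Gaussian template suffices.
#'
#' @param truth a `ground_truth`.
#' @param fs sampling rate in Hz (typically 255 for contact, 30 for camera).
#' @param pulse_width_s Gaussian sd of one pulse in seconds.
#' @param noise_sd additive white-noise sd (unit pulse amplitude scale).
#' @param seed seed for the noise draws.
#' @return a [bvp_signal()] covering the configured duration.
#' @export
beats_to_bvp <- function(truth, fs, pulse_width_s = 0.12, noise_sd = 0,
                         seed = truth$config$seed) {
  dur <- truth$config$duration_s
  if (length(truth$beat_times_ms) > 1L &&
      pulse_width_s * 1000 >= min(diff(truth$beat_times_ms)))
    warning("pulse width reaches the minimum interval; pulses overlap heavily")
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  half <- 4 * pulse_width_s
  for (tb in truth$beat_times_ms / 1000) {
    i0 <- max(1L, ceiling((tb - half) * fs) + 1L)
    i1 <- min(n, floor((tb + half) * fs) + 1L)
    if (i0 > i1) next
    seg <- i0:i1
    x[seg] <- x[seg] + exp(-((t[seg] - tb)^2) / (2 * pulse_width_s^2))
  }
  if (noise_sd > 0)
    x <- x + with_seed(seed + 7919L, rnorm(n, 0, noise_sd))
  bvp_signal(x, fs = fs)
}

#' Simulate one paired contact/camera recording
#'
#' Renders a single IPFM beat process at both channel rates. Artifacts are
#' applied to the camera channel only: the contact channel plays the
#' ground-truth reference role. Channel noise is drawn independently per
#' channel.
#'
#' @param cfg a [simulation_config()].
#' @return `list(contact = bvp_signal at fs_contact, camera = bvp_signal at
#'   fs_camera, truth = ground_truth)`. `truth$beat_times_ms` holds the
#'   clean process; `truth$camera_beat_times_ms` and
#'   `truth$artifact_indices` describe the perturbed camera process.
#' @export
simulate_dual_recording <- function(cfg = simulation_config()) {
  truth <- simulate_beats(cfg)
  cam_truth <- inject_artifacts(truth, cfg)
  contact <- beats_to_bvp(truth, cfg$fs_contact,
                          noise_sd = cfg$channel_noise_sd,
                          seed = cfg$seed + 1L)
  camera <- beats_to_bvp(cam_truth, cfg$fs_camera,
                         noise_sd = cfg$channel_noise_sd,
                         seed = cfg$seed + 2L)
  truth$camera_beat_times_ms <- cam_truth$beat_times_ms
  truth$artifact_indices <- cam_truth$artifact_indices
  list(contact = contact, camera = camera, truth = truth)
}

#' Simulate pulse-modulated skin video frames
#'
#' Produces the raw camera-channel input for [extract_bvp()]: frames with a
#' skin-colored region (inside the default [skin_config()] bounds) whose Cr
#' rises and Cb falls with the rendered pulse waveform, a static non-skin
#' background, and per-pixel Gaussian noise that dithers the 8-bit
#' quantization. Frames are quantized to integer 0-255 levels like real
#' camera output.
#'
#' @param truth a `ground_truth`.
#' @param fps frame rate (Hz).
#' @param size `c(height, width)` in pixels.
#' @param skin_fraction fraction of rows (from the top) covered by skin.
#' @param modulation_depth peak chroma excursion in channel units (<= 5;
#'   pulse-driven chroma shifts are subtle).
#' @param noise_sd per-pixel chroma/luma noise sd in channel units.
#' @param duration_s length to render (default: the full beat process).
#' @param seed seed for the pixel noise.
#' @return a [frame_sequence()].
#' @export
simulate_face_frames <- function(truth, fps = 30, size = c(40, 40),
                                 skin_fraction = 1, modulation_depth = 2,
                                 noise_sd = 2, duration_s = NULL,
                                 seed = truth$config$seed) {
  if (modulation_depth > 5)
    prv_error("prvkit_invalid_config", "modulation_depth must be <= 5 channel units")
  dur <- duration_s %||% truth$config$duration_s
  n <- round(dur * fps)
  t <- (seq_len(n) - 1) / fps
  # rendered pulse waveform, normalized to [-1, 1]-ish about zero
  pulse <- numeric(n)
  w <- 0.12
  for (tb in truth$beat_times_ms / 1000) {
    if (tb > dur + 4 * w) break
    pulse <- pulse + exp(-((t - tb)^2) / (2 * w^2))
  }
  pulse <- pulse - mean(pulse)
  if (max(abs(pulse)) > 0) pulse <- pulse / max(abs(pulse))

  h <- size[1]; wd <- size[2]
  n_skin_rows <- max(1L, round(skin_fraction * h))
  skin_rows <- seq_len(n_skin_rows)
  base_y <- 150; base_cb <- 110; base_cr <- 150    # interior of the skin bounds
  bg_rgb <- c(20, 40, 230)                          # blue background, non-skin

  with_seed(seed + 15485863L, {
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      yc <- array(0, dim = c(h, wd, 3))
      yc[, , 1] <- base_y
      yc[, , 2] <- base_cb - modulation_depth * pulse[i]
      yc[, , 3] <- base_cr + modulation_depth * pulse[i]
      rgb <- ycbcr_to_rgb(yc)
      if (n_skin_rows < h) {
        for (ch in 1:3) rgb[(n_skin_rows + 1L):h, , ch] <- bg_rgb[ch]
      }
      if (noise_sd > 0)
        rgb <- rgb + array(rnorm(h * wd * 3, 0, noise_sd), dim = c(h, wd, 3))
      rgb <- round(rgb)
      rgb[rgb < 0] <- 0; rgb[rgb > 255] <- 255
      frames[[i]] <- rgb
    }
    frame_sequence(frames, fps = fps)
  })
}
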