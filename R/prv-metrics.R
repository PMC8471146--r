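#' Frequency band definitions for PRV spectral analysis
#'
#' Standard short-term HRV bands: very low frequency (VLF) 0.0033-0.04 Hz,
#' low frequency (LF) 0.04-0.15 Hz (sympathetic and baroreflex activity) and
#' high frequency (HF) 0.15-0.4 Hz (parasympathetic, respiratory).
#'
#' @param vlf,lf,hf numeric `c(f_lo, f_hi)` band edges in Hz; the bands must
#'   be ordered with non-overlapping interiors.
#' @return a `band_definition` list.
#' @export
band_definition <- function(vlf = c(0.0033, 0.04), lf = c(0.04, 0.15),
                            hf = c(0.15, 0.4)) {
  for (b in list(vlf, lf, hf))
    if (length(b) != 2L || b[1] >= b[2])
      prv_error("prvkit_invalid_config", "each band needs f_lo < f_hi")
  if (vlf[2] > lf[1] || lf[2] > hf[1])
    prv_error("prvkit_invalid_config", "bands must be ordered and non-overlapping")
  structure(list(vlf = vlf, lf = lf, hf = hf), class = "band_definition")
}

#' Spectral-estimation configuration for the interval tachogram
#'
#' The tachogram (interval vs cumulative beat time) is resampled to a
#' uniform grid before PSD estimation; 4 Hz comfortably exceeds twice the
#' 0.4 Hz HF ceiling. The PSD uses averaged modified periodograms (Hann
#' window); a 120 s window gives ~0.008 Hz resolution, enough to separate
#' the VLF/LF boundary, while still averaging 3-4 windows over a 300 s
#' segment.
#'
#' @param resample_hz uniform tachogram rate (Hz); must exceed 0.8 Hz.
#' @param psd_window_s averaging-window length in seconds.
#' @param psd_overlap_fraction overlap of adjacent windows in `[0, 1)`.
#' @return a `spectral_config` list.
#' @export
spectral_config <- function(resample_hz = 4, psd_window_s = 120,
                            psd_overlap_fraction = 0.5) {
  if (resample_hz <= 0.8)
    prv_error("prvkit_invalid_config", "resample_hz must exceed twice the HF ceiling")
  if (psd_overlap_fraction < 0 || psd_overlap_fraction >= 1)
    prv_error("prvkit_invalid_config", "overlap must be in [0, 1)")
  structure(list(resample_hz = resample_hz, psd_window_s = psd_window_s,
                 psd_overlap_fraction = psd_overlap_fraction),
            class = "spectral_config")
}

#' Mean of the normal-to-normal intervals
#'
#' @param nni an [nni_series()], [ppi_series()] or numeric intervals (ms).
#' @return mean interval in ms.
#' @export
mean_nn <- function(nni) {
  x <- as_intervals(nni)
  if (length(x) == 0L)
    prv_error("prvkit_too_few_samples", "empty interval series")
  mean(x)
}

#' Standard deviation of the normal-to-normal intervals (SDNN)
#'
#' Population standard deviation of the segment's intervals, the classic
#' time-domain index of overall beat-to-beat variability.
#'
#' @param nni an [nni_series()], [ppi_series()] or numeric intervals (ms).
#' @return SDNN in ms.
#' @export
sdnn <- function(nni) {
  x <- as_intervals(nni)
  if (length(x) < 2L)
    prv_error("prvkit_too_few_samples", "need at least 2 intervals")
  sqrt(mean((x - mean(x))^2))
}

# Welch PSD: averaged modified periodograms with a Hann window.
# Returns one-sided density (units^2 / Hz) on frequencies 0..fs/2.
welch_psd <- function(x, fs, window_s, overlap = 0.5) {
  n <- length(x)
  nper <- min(n, max(8L, round(window_s * fs)))
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nper) - 1) / (nper - 1))
  scale <- fs * sum(w^2)
  nfreq <- floor(nper / 2) + 1L
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nfreq)]
    acc <- acc + Mod(X)^2 / scale
  }
  p <- acc / length(starts)
  # fold negative frequencies into the one-sided density
  interior <- 2:(nfreq - if (nper %% 2 == 0) 1L else 0L)
  p[interior] <- 2 * p[interior]
  list(freq = (seq_len(nfreq) - 1) * fs / nper, density = p)
}

#' Power spectral density of the interval tachogram
#'
#' Builds the tachogram (interval in ms against cumulative beat time),
#' resamples it to a uniform grid at `cfg$resample_hz` with a quadratic
#' spline (the same interpolant used for the BVP channel), removes the mean,
#' and estimates a one-sided PSD by averaged modified periodograms (Hann
#' windows of `cfg$psd_window_s` seconds at `cfg$psd_overlap_fraction`
#' overlap).
#'
#' @param nni an [nni_series()], [ppi_series()] or numeric intervals (ms).
#' @param cfg a [spectral_config()].
#' @return `list(freq, density)` with frequency in Hz and density in
#'   ms^2/Hz.
#' @export
tachogram_psd <- function(nni, cfg = spectral_config()) {
  x <- as_intervals(nni)
  t_beat <- cumsum(x) / 1000  # s, time of each interval's closing beat
  span <- t_beat[length(t_beat)] - t_beat[1]
  if (span < 2 / 0.04)
    prv_error("prvkit_too_few_samples",
              "interval series must span at least 50 s of beat time")
  t_grid <- seq(t_beat[1], t_beat[length(t_beat)], by = 1 / cfg$resample_hz)
  y <- quad_spline(t_beat, x, t_grid)
  welch_psd(y - mean(y), cfg$resample_hz, cfg$psd_window_s,
            cfg$psd_overlap_fraction)
}

#' Integrate a PSD over a frequency band
#'
#' Trapezoidal integral of the one-sided density over `[f_lo, f_hi]`, with
#' linearly interpolated ordinates at the band edges.
#'
#' @param psd `list(freq, density)` as returned by [tachogram_psd()].
#' @param band numeric `c(f_lo, f_hi)` in Hz; must lie within the PSD
#'   support.
#' @return band power (ms^2 for a tachogram PSD).
#' @export
band_power <- function(psd, band) {
  f <- psd$freq; p <- psd$density
  if (band[1] < f[1] - 1e-12 || band[2] > f[length(f)] + 1e-12)
    prv_error("prvkit_invalid_argument", "band outside the PSD support")
  inside <- f > band[1] & f < band[2]
  fi <- c(band[1], f[inside], band[2])
  pi_ <- c(approx(f, p, band[1])$y, p[inside], approx(f, p, band[2])$y)
  pracma::trapz(fi, pi_)
}

#' Normalized LF and HF units
#'
#' Expresses LF and HF power as percentages of the total power with the VLF
#' component excluded:
#' \deqn{LFnu = 100 \cdot LF / (Total - VLF), \quad
#'       HFnu = 100 \cdot HF / (Total - VLF)}
#' With total power defined as VLF + LF + HF the two normalized units sum
#' to 100.
#'
#' @param lf_power,hf_power,vlf_power,total_power band powers (ms^2);
#'   `total_power > vlf_power >= 0`.
#' @return named numeric `c(lfnu, hfnu)` in percent.
#' @export
normalized_units <- function(lf_power, hf_power, vlf_power, total_power) {
  denom <- total_power - vlf_power
  if (denom <= 0)
    prv_error("prvkit_degenerate_spectrum",
              "total power does not exceed VLF power")
  c(lfnu = 100 * lf_power / denom, hfnu = 100 * hf_power / denom)
}

#' Compute the PRV indices for one segment
#'
#' Derives the five standard indicators from an NNI segment: mean NN and
#' SDNN in the time domain; LFnu, HFnu and LF/HF from the tachogram PSD.
#' Total power is the VLF + LF + HF integral, so LFnu + HFnu = 100.
#'
#' @param nni an [nni_series()], [ppi_series()] or numeric intervals (ms);
#'   nominally one 300 s segment.
#' @param bands a [band_definition()].
#' @param cfg a [spectral_config()].
#' @return a `prv_indices` list with fields `mean_nn`, `sdnn`, `vlf_power`,
#'   `lf_power`, `hf_power`, `total_power`, `lfnu`, `hfnu`, `lf_hf`.
#' @export
compute_prv <- function(nni, bands = band_definition(), cfg = spectral_config()) {
  x <- as_intervals(nni)
  mn <- mean_nn(x)
  sdv <- sdnn(x)
  if (sdv == 0)
    prv_error("prvkit_degenerate_spectrum",
              "constant interval series has no spectral content")
  psd <- tachogram_psd(x, cfg)
  vlf <- band_power(psd, bands$vlf)
  lf <- band_power(psd, bands$lf)
  hf <- band_power(psd, bands$hf)
  if (hf == 0)
    prv_error("prvkit_degenerate_spectrum", "HF power is zero; LF/HF undefined")
  total <- vlf + lf + hf
  nu <- normalized_units(lf, hf, vlf, total)
  structure(list(mean_nn = mn, sdnn = sdv, vlf_power = vlf, lf_power = lf,
                 hf_power = hf, total_power = total,
                 lfnu = unname(nu["lfnu"]), hfnu = unname(nu["hfnu"]),
                 lf_hf = lf / hf),
            class = "prv_indices")
}

#' @export
print.prv_indices <- function(x, ...) {
  cat(sprintf(paste0("<prv_indices> mean NN %.1f ms | SDNN %.1f ms | ",
                     "LFnu %.1f%% | HFnu %.1f%% | LF/HF %.2f\n"),
              x$mean_nn, x$sdnn, x$lfnu, x$hfnu, x$lf_hf))
  invisible(x)
}

#' PRV indices for every segment of a pipeline run
#'
#' Applies [compute_prv()] to each segment of a [run_ppi_pipeline()] result,
#' using either the normalized (NNI) or the raw (PPI) intervals.
#'
#' @param segments list returned by [run_ppi_pipeline()].
#' @param use `"nni"` (default) or `"ppi"`.
#' @param bands a [band_definition()].
#' @param cfg a [spectral_config()].
#' @return data frame with columns `segment`, `mean_nn`, `sdnn`, `lfnu`,
#'   `hfnu`, `lf_hf`.
#' @export
segment_indicators <- function(segments, use = c("nni", "ppi"),
                               bands = band_definition(),
                               cfg = spectral_config()) {
  use <- match.arg(use)
  rows <- lapply(seq_along(segments), function(i) {
    p <- compute_prv(segments[[i]][[use]], bands, cfg)
    data.frame(segment = i, mean_nn = p$mean_nn, sdnn = p$sdnn,
               lfnu = p$lfnu, hfnu = p$hfnu, lf_hf = p$lf_hf)
  })
  do.call(rbind, rows)
}
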