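#' Cropping and overlapped-segmentation specification
#'
#' An 11 min recording is cropped by 30 s at each end (settling time around
#' the start and end of a measurement) to 10 min, then cut into overlapped
#' 300 s analysis windows. With the default 30 s stride, 600 s of signal
#' yields `(600 - 300)/30 + 1 = 11` segments per recording.
#'
#' @param window_s segment length in seconds (> 0).
#' @param stride_s hop between segment starts in seconds; `0 < stride_s <=
#'   window_s`.
#' @param crop_head_s,crop_tail_s seconds removed from each end before
#'   segmentation.
#' @return a `segment_spec` list.
#' @export
segment_spec <- function(window_s = 300, stride_s = 30,
                         crop_head_s = 30, crop_tail_s = 30) {
  if (window_s <= 0 || stride_s <= 0 || stride_s > window_s)
    prv_error("prvkit_invalid_config", "need 0 < stride_s <= window_s and window_s > 0")
  if (crop_head_s < 0 || crop_tail_s < 0)
    prv_error("prvkit_invalid_config", "crop amounts must be >= 0")
  structure(list(window_s = window_s, stride_s = stride_s,
                 crop_head_s = crop_head_s, crop_tail_s = crop_tail_s),
            class = "segment_spec")
}

#' Interval-cleaning configuration
#'
#' Parameters for peak detection and PPI -> NNI normalization. The z-score
#' threshold `T = 2` marks an interval as abnormal when it lies two (population)
#' standard deviations from the segment mean; the 0.5 s refractory period is
#' the shortest interval a 2 Hz upper pulse band allows.
#'
#' @param z_threshold z-score cutoff (dimensionless, > 0).
#' @param fs_target resampling rate in Hz for peak detection; must exceed
#'   twice the upper band edge.
#' @param band pulse passband `c(f_lo, f_hi)` in Hz.
#' @param min_peak_separation_s refractory period between detected peaks (s).
#' @return a `clean_config` list.
#' @export
clean_config <- function(z_threshold = 2, fs_target = 255,
                         band = c(0.5, 2.0), min_peak_separation_s = 0.5) {
  if (z_threshold <= 0)
    prv_error("prvkit_invalid_config", "z_threshold must be > 0")
  if (fs_target <= 2 * band[2])
    prv_error("prvkit_invalid_config", "fs_target must exceed twice the upper band edge")
  structure(list(z_threshold = z_threshold, fs_target = fs_target,
                 band = band, min_peak_separation_s = min_peak_separation_s),
            class = "clean_config")
}

#' Crop the head and tail of a BVP signal
#'
#' Removes `head_s` seconds from the start and `tail_s` from the end,
#' shifting `t0` accordingly: an 11 min recording cropped by 30 s at each
#' end spans exactly 10 min.
#'
#' @param bvp a [bvp_signal()].
#' @param head_s,tail_s seconds to remove from each end.
#' @return the interior `bvp_signal`.
#' @export
crop_signal <- function(bvp, head_s = 30, tail_s = 30) {
  stopifnot(inherits(bvp, "bvp_signal"))
  if (head_s == 0 && tail_s == 0) return(bvp)
  n <- length(bvp$samples)
  i0 <- round(head_s * bvp$fs) + 1L
  i1 <- n - round(tail_s * bvp$fs)
  if (i1 - i0 + 1L < 2L)
    prv_error("prvkit_too_few_samples",
              sprintf("signal (%.1f s) too short to crop %g + %g s",
                      duration(bvp), head_s, tail_s))
  bvp_signal(bvp$samples[i0:i1], fs = bvp$fs, t0 = bvp$t0 + head_s)
}

#' Split a signal into overlapped segments
#'
#' Segments start at offsets `0, stride_s, 2 stride_s, ...` and are each
#' exactly `window_s` long; the count is
#' `floor((duration - window_s) / stride_s) + 1`.
#'
#' @param bvp a [bvp_signal()].
#' @param spec a [segment_spec()] (its crop fields are ignored here; see
#'   [run_ppi_pipeline()] for the full chain).
#' @return list of `bvp_signal` segments.
#' @export
segment_overlapped <- function(bvp, spec = segment_spec()) {
  stopifnot(inherits(bvp, "bvp_signal"))
  dur <- duration(bvp)
  if (dur < spec$window_s)
    prv_error("prvkit_too_few_samples",
              sprintf("signal (%.1f s) shorter than the %g s window", dur, spec$window_s))
  n_win <- round(spec$window_s * bvp$fs)
  n_hop <- round(spec$stride_s * bvp$fs)
  n_seg <- floor((length(bvp$samples) - n_win) / n_hop) + 1L
  lapply(seq_len(n_seg) - 1L, function(k) {
    i0 <- k * n_hop + 1L
    bvp_signal(bvp$samples[i0:(i0 + n_win - 1L)], fs = bvp$fs,
               t0 = bvp$t0 + k * spec$stride_s)
  })
}

#' Detect pulse peaks in a bandpassed BVP segment
#'
#' Local maxima above zero separated by at least the refractory period
#' (`min_peak_separation_s`); when two candidates fall inside one refractory
#' window the larger wins. Times are reported at sample resolution.
#'
#' @param bvp a bandpassed [bvp_signal()].
#' @param config a [clean_config()].
#' @return numeric vector of peak times in milliseconds (absolute, i.e.
#'   including `t0`); errors with class `prvkit_no_peaks` when none exist.
#' @export
detect_peaks <- function(bvp, config = clean_config()) {
  stopifnot(inherits(bvp, "bvp_signal"))
  min_dist <- max(1L, round(config$min_peak_separation_s * bvp$fs))
  pk <- pracma::findpeaks(bvp$samples, minpeakheight = 0,
                          minpeakdistance = min_dist)
  if (is.null(pk) || nrow(pk) == 0L)
    prv_error("prvkit_no_peaks", "no peaks found in segment")
  idx <- sort(pk[, 2])
  (bvp$t0 + (idx - 1) / bvp$fs) * 1000
}

#' Peak times to a PPI series
#'
#' Successive differences of the detected beat times.
#'
#' @param peak_times_ms strictly increasing peak times in ms (>= 2).
#' @return a [ppi_series()].
#' @export
peaks_to_ppi <- function(peak_times_ms) {
  ppi_series(peak_times_ms)
}

#' Normalize a PPI series to an NNI series
#'
#' Computes z-scores of the segment's intervals against the segment mean and
#' population standard deviation (statistics from the unmodified series,
#' computed once). Every interval with `|z| >= z_threshold` is replaced, in a
#' single pass in index order, by the median of its immediate front and back
#' neighbors in the partially cleaned series (for two values the median is
#' their mean; at the series boundaries the single available neighbor is
#' used). Abnormally short and long intervals are treated symmetrically.
#' A zero-variance series has no definable outliers and is returned
#' unchanged.
#'
#' @param ppi a [ppi_series()] (or numeric intervals) with >= 3 intervals.
#' @param config a [clean_config()]; only `z_threshold` is used.
#' @return an [nni_series()] of the same length, with `replaced_indices`.
#' @export
ppi_to_nni <- function(ppi, config = clean_config()) {
  x <- as_intervals(ppi)
  if (length(x) < 3L)
    prv_error("prvkit_too_few_samples", "need at least 3 intervals")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(nni_series(x))
  z <- (x - m) / s
  out <- which(abs(z) >= config$z_threshold)
  y <- x
  n <- length(x)
  for (i in out) {
    front <- if (i > 1L) y[i - 1L] else NULL
    back <- if (i < n) x[i + 1L] else NULL
    y[i] <- median(c(front, back))
  }
  nni_series(y, replaced_indices = out)
}

#' Full BVP-to-NNI pipeline
#'
#' Runs the complete interval-extraction chain on one recording: crop the
#' head and tail, cut into overlapped segments, resample each segment to
#' `fs_target` with a quadratic spline (skipped when the signal is already
#' at or above the target rate), bandpass to the pulse band with a
#' zero-phase Butterworth filter, detect peaks, form the PPI series, and
#' normalize it to NNI by the z-score rule.
#'
#' @param bvp a [bvp_signal()] (e.g. a 660 s contact or camera recording).
#' @param spec a [segment_spec()].
#' @param config a [clean_config()].
#' @return a list with one element per segment, each
#'   `list(ppi = ppi_series, nni = nni_series)`.
#' @export
run_ppi_pipeline <- function(bvp, spec = segment_spec(), config = clean_config()) {
  cropped <- crop_signal(bvp, spec$crop_head_s, spec$crop_tail_s)
  segments <- segment_overlapped(cropped, spec)
  lapply(segments, function(seg) {
    if (seg$fs < config$fs_target)
      seg <- resample_quadratic_spline(seg, config$fs_target)
    filt <- bvp_signal(bandpass_butterworth(seg$samples, seg$fs,
                                            config$band[1], config$band[2]),
                       fs = seg$fs, t0 = seg$t0)
    peaks <- detect_peaks(filt, config)
    ppi <- peaks_to_ppi(peaks)
    list(ppi = ppi, nni = ppi_to_nni(ppi, config))
  })
}
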