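#' Uniformly sampled blood volume pulse signal
#'
#' Container for a BVP trace: an amplitude series sampled at a fixed rate.
#' Amplitudes are in arbitrary units (zero-mean after filtering); `t0` is the
#' absolute time of the first sample in seconds.
#'
#' @param samples numeric vector of amplitudes (length >= 2, finite).
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @return An object of class `bvp_signal` with fields `samples`, `fs`, `t0`.
#' @examples
#' b <- bvp_signal(sin(2 * pi * seq(0, 10, by = 1 / 30)), fs = 30)
#' duration(b)
#' @export
bvp_signal <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    prv_error("prvkit_invalid_signal", "a BVP signal needs at least 2 samples")
  if (!all(is.finite(samples)))
    prv_error("prvkit_invalid_signal", "BVP samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    prv_error("prvkit_invalid_signal", "fs must be a single positive number")
  structure(list(samples = samples, fs = fs, t0 = as.numeric(t0)),
            class = "bvp_signal")
}

#' @export
print.bvp_signal <- function(x, ...) {
  cat(sprintf("<bvp_signal> %d samples @ %g Hz, %.2f s (t0 = %.2f s)\n",
              length(x$samples), x$fs, duration(x), x$t0))
  invisible(x)
}

#' Signal duration in seconds
#'
#' Duration is measured on the sample grid: `n / fs`, so that a 30 s signal
#' at 30 Hz holds exactly 900 samples.
#'
#' @param x a `bvp_signal`.
#' @return duration in seconds.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.bvp_signal <- function(x) length(x$samples) / x$fs

#' Sample times of a BVP signal
#'
#' @param x a `bvp_signal`.
#' @return numeric vector of times in seconds (`t0 + (0:(n-1))/fs`).
#' @export
sample_times <- function(x) {
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' Peak-to-peak interval series
#'
#' Beat times (ms, strictly increasing) with their successive differences,
#' the raw inter-beat intervals before any outlier handling.
#'
#' @param peak_times_ms strictly increasing beat times in milliseconds.
#' @return `ppi_series` with fields `peak_times_ms`, `intervals_ms`.
#' @export
ppi_series <- function(peak_times_ms) {
  peak_times_ms <- as.numeric(peak_times_ms)
  if (length(peak_times_ms) < 2L)
    prv_error("prvkit_too_few_peaks", "need at least 2 peaks to form intervals")
  d <- diff(peak_times_ms)
  if (any(d <= 0))
    prv_error("prvkit_invalid_series", "peak times must be strictly increasing")
  structure(list(peak_times_ms = peak_times_ms, intervals_ms = d),
            class = "ppi_series")
}

#' @export
print.ppi_series <- function(x, ...) {
  cat(sprintf("<ppi_series> %d intervals, mean %.1f ms\n",
              length(x$intervals_ms), mean(x$intervals_ms)))
  invisible(x)
}

#' Normal-to-normal interval series
#'
#' A PPI series after z-score outlier replacement ("normalization").
#' Same length as its source intervals; `replaced_indices` marks positions
#' whose value was substituted.
#'
#' @param intervals_ms normalized intervals in milliseconds (> 0).
#' @param replaced_indices integer positions that were replaced.
#' @return `nni_series` with fields `intervals_ms`, `replaced_indices`.
#' @export
nni_series <- function(intervals_ms, replaced_indices = integer(0)) {
  intervals_ms <- as.numeric(intervals_ms)
  if (any(intervals_ms <= 0))
    prv_error("prvkit_invalid_series", "intervals must be positive")
  structure(list(intervals_ms = intervals_ms,
                 replaced_indices = as.integer(replaced_indices)),
            class = "nni_series")
}

#' @export
print.nni_series <- function(x, ...) {
  cat(sprintf("<nni_series> %d intervals, %d replaced, mean %.1f ms\n",
              length(x$intervals_ms), length(x$replaced_indices),
              mean(x$intervals_ms)))
  invisible(x)
}

# Accept nni_series, ppi_series or a bare numeric vector of intervals.
as_intervals <- function(x) {
  if (inherits(x, "nni_series")) return(x$intervals_ms)
  if (inherits(x, "ppi_series")) return(x$intervals_ms)
  if (is.numeric(x)) return(as.numeric(x))
  prv_error("prvkit_invalid_series", "expected an interval series or numeric vector")
}

#' Ordered RGB frame sequence
#'
#' The raw camera-channel input: a list of H x W x 3 arrays (8-bit scale,
#' values in [0, 255]) sharing dimensions, a frame rate, and an optional
#' region of interest.
#'
#' @param frames list of H x W x 3 numeric arrays on the 0-255 scale.
#' @param fps frames per second (> 0).
#' @param roi optional `c(x, y, w, h)` rectangle in pixel coordinates
#'   (origin top-left, x along columns); must lie within frame bounds.
#' @return `frame_sequence` object.
#' @export
frame_sequence <- function(frames, fps, roi = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    prv_error("prvkit_invalid_frames", "frames must be a non-empty list")
  dims <- dim(frames[[1]])
  if (length(dims) != 3L || dims[3] != 3L)
    prv_error("prvkit_invalid_frames", "each frame must be an H x W x 3 array")
  for (f in frames) {
    if (!identical(dim(f), dims))
      prv_error("prvkit_invalid_frames", "all frames must share dimensions")
  }
  if (fps <= 0)
    prv_error("prvkit_invalid_frames", "fps must be positive")
  if (!is.null(roi)) {
    roi <- as.numeric(roi)
    if (length(roi) != 4L || roi[1] < 0 || roi[2] < 0 ||
        roi[1] + roi[3] > dims[2] || roi[2] + roi[4] > dims[1] ||
        roi[3] < 1 || roi[4] < 1)
      prv_error("prvkit_invalid_frames", "roi must be c(x, y, w, h) within frame bounds")
  }
  structure(list(frames = frames, fps = fps, roi = roi),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames of %dx%d @ %g fps%s\n",
              length(x$frames), d[1], d[2], x$fps,
              if (is.null(x$roi)) "" else sprintf(", roi [%s]",
                                                  paste(x$roi, collapse = ","))))
  invisible(x)
}

# Crop a frame to the sequence ROI (if any).
apply_roi <- function(frame, roi) {
  if (is.null(roi)) return(frame)
  rows <- (roi[2] + 1):(roi[2] + roi[4])
  cols <- (roi[1] + 1):(roi[1] + roi[3])
  frame[rows, cols, , drop = FALSE]
}
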