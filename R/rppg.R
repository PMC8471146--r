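#' Skin-detection and chrominance-expansion configuration
#'
#' Parameters governing skin-pixel selection in YCbCr space and the random
#' expansion of the per-frame chrominance cluster center. The default bounds
#' (Y >= 40, 77 <= Cb <= 127, 133 <= Cr <= 173) are a widely used published
#' YCbCr skin range; all are user-configurable because skin chromaticity
#' varies with subject and illumination.
#'
#' @param y_min minimum luma (8-bit scale).
#' @param cb_min,cb_max blue-difference chroma bounds; `cb_min < cb_max`.
#' @param cr_min,cr_max red-difference chroma bounds; `cr_min < cr_max`.
#' @param n_expansion number of random expansions of the cluster center
#'   per frame (>= 1).
#' @param expansion_scale dispersion (standard deviation, channel units) of
#'   the isotropic Gaussian expansion.
#' @param seed random seed used by [extract_bvp()] for the expansion draws.
#' @return a `skin_config` list.
#' @export
skin_config <- function(y_min = 40, cb_min = 77, cb_max = 127,
                        cr_min = 133, cr_max = 173,
                        n_expansion = 100L, expansion_scale = 1.0,
                        seed = 1L) {
  if (cb_min >= cb_max || cr_min >= cr_max)
    prv_error("prvkit_invalid_config", "chroma bounds must satisfy min < max")
  if (n_expansion < 1L)
    prv_error("prvkit_invalid_config", "n_expansion must be >= 1")
  if (expansion_scale < 0)
    prv_error("prvkit_invalid_config", "expansion_scale must be >= 0")
  structure(list(y_min = y_min, cb_min = cb_min, cb_max = cb_max,
                 cr_min = cr_min, cr_max = cr_max,
                 n_expansion = as.integer(n_expansion),
                 expansion_scale = expansion_scale, seed = seed),
            class = "skin_config")
}

#' Convert an RGB frame to YCbCr
#'
#' Applies the ITU-R BT.601 full-range ("JPEG") transform per pixel:
#' \deqn{Y = 0.299R + 0.587G + 0.114B}
#' \deqn{Cb = 128 - 0.168736R - 0.331264G + 0.5B}
#' \deqn{Cr = 128 + 0.5R - 0.418688G - 0.081312B}
#' Values are clipped to \[0, 255\]. Achromatic pixels (R = G = B = v) map to
#' (v, 128, 128).
#'
#' @param frame H x W x 3 numeric array, 8-bit scale (0-255).
#' @return H x W x 3 array with channels Y, Cb, Cr.
#' @export
rgb_to_ycbcr <- function(frame) {
  d <- dim(frame)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    prv_error("prvkit_invalid_frames", "frame must be an H x W x 3 RGB array")
  r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
  out <- array(0, dim = d)
  out[, , 1] <- 0.299 * r + 0.587 * g + 0.114 * b
  out[, , 2] <- 128 - 0.168736 * r - 0.331264 * g + 0.5 * b
  out[, , 3] <- 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

# Inverse full-range BT.601 (used by the frame simulator).
ycbcr_to_rgb <- function(frame) {
  y <- frame[, , 1]; cb <- frame[, , 2] - 128; cr <- frame[, , 3] - 128
  out <- array(0, dim = dim(frame))
  out[, , 1] <- y + 1.402 * cr
  out[, , 2] <- y - 0.344136 * cb - 0.714136 * cr
  out[, , 3] <- y + 1.772 * cb
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Skin-pixel mask from a YCbCr frame
#'
#' A pixel is skin exactly when `Y >= y_min`, `cb_min <= Cb <= cb_max` and
#' `cr_min <= Cr <= cr_max`.
#'
#' @param ycbcr_frame H x W x 3 YCbCr array (see [rgb_to_ycbcr()]).
#' @param config a [skin_config()].
#' @return logical H x W matrix; errors with class `prvkit_no_skin` when no
#'   pixel qualifies.
#' @export
skin_mask <- function(ycbcr_frame, config = skin_config()) {
  y <- ycbcr_frame[, , 1]; cb <- ycbcr_frame[, , 2]; cr <- ycbcr_frame[, , 3]
  mask <- y >= config$y_min &
    cb >= config$cb_min & cb <= config$cb_max &
    cr >= config$cr_min & cr <= config$cr_max
  if (!any(mask))
    prv_error("prvkit_no_skin", "no skin pixels found in frame")
  mask
}

#' Centroid of skin pixels on the Cb-Cr plane
#'
#' The per-frame chrominance cluster center P(Cb-center, Cr-center): the
#' arithmetic mean of the skin pixels' (Cb, Cr) values.
#'
#' @param cb,cr numeric vectors of skin-pixel chroma values (equal length,
#'   >= 1 pixel).
#' @return named numeric `c(cb, cr)`.
#' @export
cluster_center <- function(cb, cr) {
  if (length(cb) == 0L || length(cb) != length(cr))
    prv_error("prvkit_invalid_argument", "need equal-length non-empty cb and cr")
  c(cb = mean(cb), cr = mean(cr))
}

#' Random expansion of a chrominance cluster center
#'
#' Draws `n_expansion` isotropic Gaussian offsets (sd `expansion_scale`)
#' around the center and returns the mean of the expanded Cb and Cr samples.
#' The expansion thickens the skin-chroma distribution so that the subtle
#' pulse-driven chroma shift is less easily swamped by quantization; it is
#' a spatial expansion, so [extract_bvp()] draws one offset set per
#' extraction and reuses it for every frame (identical frames therefore
#' yield identical chroma, and a static scene propagates a degenerate-signal
#' error instead of expansion noise). Draws come from the session RNG
#' stream unless precomputed `offsets` are supplied; `extract_bvp()` seeds
#' the stream once from `config$seed`, making extraction bit-reproducible.
#'
#' @param center numeric `c(cb, cr)` cluster center.
#' @param config a [skin_config()].
#' @param offsets optional `list(cb=, cr=)` of precomputed offset vectors
#'   (length `n_expansion`) to reuse across frames.
#' @return named numeric `c(cb, cr)`: means of the expanded samples.
#' @export
random_expansion <- function(center, config = skin_config(), offsets = NULL) {
  n <- config$n_expansion
  s <- config$expansion_scale
  if (s == 0) return(c(cb = unname(center[1]), cr = unname(center[2])))
  if (is.null(offsets))
    offsets <- list(cb = rnorm(n, 0, s), cr = rnorm(n, 0, s))
  c(cb = unname(center[1]) + mean(offsets$cb),
    cr = unname(center[2]) + mean(offsets$cr))
}

#' Combine expanded chrominance series into a raw BVP
#'
#' The pulse raises Cr and lowers Cb as blood volume peaks, so the
#' standardized difference `z(Cr) - z(Cb)` reinforces the pulse component
#' while cancelling common-mode illumination drift. Each series is
#' standardized to zero mean / unit variance; a constant series contributes
#' zero (its variance carries no pulse information).
#'
#' @param cb_series,cr_series equal-length numeric series (length >= 2).
#' @return zero-mean numeric BVP samples; errors with class
#'   `prvkit_degenerate_signal` if both series are constant.
#' @export
chrominance_to_bvp <- function(cb_series, cr_series) {
  if (length(cb_series) != length(cr_series) || length(cb_series) < 2L)
    prv_error("prvkit_invalid_argument", "need equal-length series of length >= 2")
  zb <- standardize_or_zero(cb_series)
  zr <- standardize_or_zero(cr_series)
  if (is.null(zb) && is.null(zr))
    prv_error("prvkit_degenerate_signal",
              "both chrominance series are constant; no pulse information")
  out <- (zr %||% 0) - (zb %||% 0)
  out - mean(out)
}

standardize_or_zero <- function(x) {
  s <- sd(x)
  if (s == 0) return(NULL)
  (x - mean(x)) / s
}

#' Remove the respiration trend from a raw BVP
#'
#' Subtracts a centered moving average whose window spans one period of the
#' slowest pulse-band component (window = `fs / 0.4` samples, about 2.5 s),
#' suppressing sub-0.4 Hz baseline wander such as breathing while leaving
#' the 0.5-2 Hz pulse band essentially untouched. Edges use shrinking
#' (partial) windows; the output is re-centered to zero mean.
#'
#' @param samples numeric raw BVP samples.
#' @param fs sampling rate (Hz).
#' @return detrended, zero-mean numeric vector of the same length.
#' @export
detrend_respiration <- function(samples, fs) {
  w <- max(3L, round(fs / 0.4))
  n <- length(samples)
  if (n <= w)
    prv_error("prvkit_too_few_samples",
              sprintf("signal (%d samples) must exceed the %d-sample detrend window", n, w))
  half <- floor(w / 2)
  cs <- cumsum(c(0, samples))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  trend <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out <- samples - trend
  out - mean(out)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Order-`order` Butterworth bandpass applied forward and backward
#' (`signal::filtfilt`), squaring the magnitude response and cancelling the
#' phase so that peak timing is not shifted by filtering.
#'
#' @param samples numeric signal.
#' @param fs sampling rate (Hz).
#' @param f_lo,f_hi passband edges (Hz); `0 < f_lo < f_hi < fs/2`.
#' @param order filter order (default 4).
#' @return filtered numeric vector of the same length.
#' @export
bandpass_butterworth <- function(samples, fs, f_lo = 0.5, f_hi = 2.0, order = 4L) {
  if (f_lo <= 0 || f_hi <= f_lo)
    prv_error("prvkit_invalid_argument", "need 0 < f_lo < f_hi")
  if (f_hi >= fs / 2)
    prv_error("prvkit_invalid_argument", "f_hi must be below the Nyquist rate fs/2")
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, samples)
}

#' Extract a BVP signal from skin video frames
#'
#' The camera-channel front end: each frame is converted to YCbCr
#' ([rgb_to_ycbcr()]), skin pixels are selected ([skin_mask()]), their
#' Cb-Cr centroid is taken ([cluster_center()]) and randomly expanded
#' ([random_expansion()]); the per-frame expanded chroma series are combined
#' into one raw BVP ([chrominance_to_bvp()]), respiration-detrended
#' ([detrend_respiration()]) and bandpassed to the pulse band
#' ([bandpass_butterworth()], 0.5-2 Hz). Frames without detectable skin are
#' filled by linear interpolation of neighboring chroma samples, keeping the
#' time base uniform; more than 10% such frames aborts with an
#' extraction-quality error. With `config$seed` fixed the extraction is
#' bit-reproducible.
#'
#' @param frames a [frame_sequence()] (the ROI, if set, restricts analysis).
#' @param config a [skin_config()].
#' @param band pulse passband in Hz (default `c(0.5, 2)`).
#' @return a [bvp_signal()] at the frame rate.
#' @export
extract_bvp <- function(frames, config = skin_config(), band = c(0.5, 2.0)) {
  stopifnot(inherits(frames, "frame_sequence"))
  n <- length(frames$frames)
  if (n < 2L)
    prv_error("prvkit_invalid_frames", "need at least 2 frames")

  if (!is.null(config$seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(config$seed)
  }

  offsets <- if (config$expansion_scale > 0)
    list(cb = rnorm(config$n_expansion, 0, config$expansion_scale),
         cr = rnorm(config$n_expansion, 0, config$expansion_scale))

  cb <- rep(NA_real_, n)
  cr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fr <- apply_roi(frames$frames[[i]], frames$roi)
    yc <- rgb_to_ycbcr(fr)
    mask <- tryCatch(skin_mask(yc, config),
                     prvkit_no_skin = function(e) NULL)
    if (is.null(mask)) next
    ctr <- cluster_center(yc[, , 2][mask], yc[, , 3][mask])
    ex <- random_expansion(ctr, config, offsets)
    cb[i] <- ex["cb"]
    cr[i] <- ex["cr"]
  }

  n_missing <- sum(is.na(cb))
  if (n_missing > 0.10 * n)
    prv_error("prvkit_extraction_quality",
              sprintf("%d of %d frames (%.0f%%) lack detectable skin",
                      n_missing, n, 100 * n_missing / n))
  if (n_missing > 0) {
    idx <- seq_len(n)
    cb <- approx(idx[!is.na(cb)], cb[!is.na(cb)], idx, rule = 2)$y
    cr <- approx(idx[!is.na(cr)], cr[!is.na(cr)], idx, rule = 2)$y
  }

  raw <- chrominance_to_bvp(cb, cr)
  det <- detrend_respiration(raw, frames$fps)
  filt <- bandpass_butterworth(det, frames$fps, band[1], band[2])
  bvp_signal(filt, fs = frames$fps)
}

#' Dominant frequency of a signal
#'
#' Location (Hz) of the largest periodogram ordinate above DC; a convenience
#' used to verify pulse-frequency recovery.
#'
#' @param x numeric samples or a [bvp_signal()].
#' @param fs sampling rate (ignored when `x` is a `bvp_signal`).
#' @return frequency in Hz.
#' @export
dominant_frequency <- function(x, fs = NULL) {
  if (inherits(x, "bvp_signal")) {
    fs <- x$fs
    x <- x$samples
  }
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- 2:floor(n / 2)
  freqs[half][which.max(p[half])]
}
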