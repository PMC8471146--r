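#' Read a BVP signal from CSV
#'
#' Expects a header `t_ms,value` with strictly increasing times. The
#' sampling rate is inferred from the median inter-sample spacing; a gap
#' exceeding twice the nominal spacing is rejected (the pipeline assumes a
#' uniform time base).
#'
#' @param path CSV file path.
#' @return a [bvp_signal()].
#' @export
read_bvp_csv <- function(path) {
  if (!file.exists(path))
    prv_error("prvkit_io", sprintf("file not found: %s", path))
  df <- read.csv(path)
  if (!identical(names(df)[1:2], c("t_ms", "value")))
    prv_error("prvkit_io", sprintf("%s: expected header t_ms,value", path))
  if (nrow(df) < 2L)
    prv_error("prvkit_io", sprintf("%s: need at least 2 rows", path))
  d <- diff(df$t_ms)
  bad <- which(d <= 0)
  if (length(bad))
    prv_error("prvkit_io",
              sprintf("%s: non-increasing t_ms at data line %d", path, bad[1] + 1L))
  nominal <- median(d)
  gap <- which(d > 2 * nominal)
  if (length(gap))
    prv_error("prvkit_io",
              sprintf("%s: gap of %.1f ms (nominal %.1f ms) at data line %d",
                      path, d[gap[1]], nominal, gap[1] + 1L))
  bvp_signal(df$value, fs = 1000 / nominal, t0 = df$t_ms[1] / 1000)
}

#' Write a BVP signal to CSV
#'
#' Inverse of [read_bvp_csv()]: header `t_ms,value`, one row per sample.
#'
#' @param bvp a [bvp_signal()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bvp_csv <- function(bvp, path) {
  stopifnot(inherits(bvp, "bvp_signal"))
  df <- data.frame(t_ms = sample_times(bvp) * 1000, value = bvp$samples)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an interval series to CSV
#'
#' Header `peak_time_ms,interval_ms`; one row per interval, stamped with the
#' time of the interval's closing beat.
#'
#' @param x a [ppi_series()] or [nni_series()]; an `nni_series` needs
#'   `peak_times_ms` supplied (it stores intervals only).
#' @param path output file path.
#' @param peak_times_ms closing-beat times for an `nni_series`.
#' @return `path`, invisibly.
#' @export
write_interval_csv <- function(x, path, peak_times_ms = NULL) {
  iv <- as_intervals(x)
  pt <- if (inherits(x, "ppi_series")) x$peak_times_ms[-1] else peak_times_ms
  if (is.null(pt)) pt <- cumsum(iv)
  write.csv(data.frame(peak_time_ms = pt, interval_ms = iv),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serializes a report (e.g. a `prv_agreement_report`, a [compute_prv()]
#' result, or any list) with a schema version, the resolved configuration
#' and the seed, so every output records its provenance.
#'
#' @param report list-like object to serialize.
#' @param path output JSON path.
#' @param config optional configuration list to embed.
#' @param seed optional seed to embed.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, config = NULL, seed = NULL) {
  payload <- list(schema_version = "1.0",
                  generated = "prvkit",
                  seed = seed,
                  config = strip_classes(config),
                  report = strip_classes(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path JSON file path.
#' @return the deserialized payload list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# jsonlite serializes plain lists/data.frames cleanly; drop S3 classes and
# attributes that would confuse round-tripping.
strip_classes <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "mape_table")) {
    return(list(rows = as.data.frame(unclass(x)[names(x)]),
                column_means = as.list(attr(x, "column_means"))))
  }
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

#' Read an ordered PNG frame directory as a frame sequence
#'
#' Frames are read in lexicographic filename order (name them
#' `frame_000001.png` ... to keep order stable); all frames must share
#' dimensions. Pixel values are rescaled from the PNG 0-1 range to the
#' 0-255 working scale.
#'
#' @param path directory containing `.png` files.
#' @param fps frame rate to attach (Hz).
#' @param roi optional `c(x, y, w, h)` region of interest.
#' @return a [frame_sequence()].
#' @export
read_frames <- function(path, fps, roi = NULL) {
  if (!dir.exists(path))
    prv_error("prvkit_io", sprintf("frame directory not found: %s", path))
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    prv_error("prvkit_io", sprintf("no .png frames in %s", path))
  frames <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
    a * 255
  })
  dims <- lapply(frames, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1L)
    prv_error("prvkit_io", "mixed frame sizes in directory")
  frame_sequence(frames, fps = fps, roi = roi)
}

#' Write a frame sequence as numbered PNG files
#'
#' @param frames a [frame_sequence()].
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  stopifnot(inherits(frames, "frame_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames$frames)) {
    png::writePNG(frames$frames[[i]] / 255,
                  file.path(path, sprintf("frame_%06d.png", i)))
  }
  invisible(path)
}
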