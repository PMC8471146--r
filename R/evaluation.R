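#' Mean absolute percentage error
#'
#' \deqn{MAPE = \frac{100}{n} \sum_{i=1}^{n} \frac{|x_i - \hat x_i|}{x_i}}
#' where `x` is the reference (contact-channel) indicator across the n data
#' segments and `x_hat` the test (camera-channel) value. Scale-invariant:
#' `mape(c*x, c*xhat) == mape(x, xhat)` for c > 0.
#'
#' @param reference numeric reference values (nonzero).
#' @param test numeric test values, same length.
#' @return MAPE in percent (>= 0 for positive references).
#' @export
mape <- function(reference, test) {
  if (length(reference) != length(test) || length(reference) == 0L)
    prv_error("prvkit_invalid_argument", "reference and test must be equal-length, non-empty")
  if (any(reference == 0))
    prv_error("prvkit_invalid_argument", "reference values must be nonzero")
  100 * mean(abs(reference - test) / reference)
}

prv_indicator_names <- c("mean_nn", "sdnn", "lfnu", "hfnu", "lf_hf")

#' Build a per-subject MAPE table
#'
#' One MAPE per (subject, indicator), scored across that subject's data
#' segments, with the per-indicator column means appended. Inputs are
#' indicator data frames (columns `subject`, `segment`, `mean_nn`, `sdnn`,
#' `lfnu`, `hfnu`, `lf_hf`) for the reference and test channels; subjects
#' and segment counts must match.
#'
#' @param ref,test indicator data frames as produced by
#'   [segment_indicators()] plus a `subject` column (any single value works
#'   for a one-subject comparison).
#' @return a `mape_table`: data frame of per-subject rows with attribute
#'   `column_means` (named numeric).
#' @export
build_mape_table <- function(ref, test) {
  if (!"subject" %in% names(ref)) ref$subject <- 1L
  if (!"subject" %in% names(test)) test$subject <- 1L
  subjects <- sort(unique(ref$subject))
  if (!identical(subjects, sort(unique(test$subject))))
    prv_error("prvkit_invalid_argument", "reference and test subjects differ")
  rows <- lapply(subjects, function(s) {
    r <- ref[ref$subject == s, , drop = FALSE]
    t <- test[test$subject == s, , drop = FALSE]
    r <- r[order(r$segment), , drop = FALSE]
    t <- t[order(t$segment), , drop = FALSE]
    if (!identical(r$segment, t$segment))
      prv_error("prvkit_invalid_argument",
                sprintf("segment mismatch for subject %s", s))
    vals <- vapply(prv_indicator_names,
                   function(ind) mape(r[[ind]], t[[ind]]), numeric(1))
    cbind(data.frame(subject = s), as.data.frame(as.list(vals)))
  })
  out <- do.call(rbind, rows)
  mape_table(out)
}

#' Construct a MAPE table from per-subject rows
#'
#' Attaches recomputed column means to a data frame of per-subject MAPE
#' values; also the way transcribed published tables are wrapped.
#'
#' @param rows data frame with a `subject` column and one column per
#'   indicator (`mean_nn`, `sdnn`, `lfnu`, `hfnu`, `lf_hf`), entries >= 0.
#' @return a `mape_table` data frame with attribute `column_means`.
#' @export
mape_table <- function(rows) {
  miss <- setdiff(c("subject", prv_indicator_names), names(rows))
  if (length(miss))
    prv_error("prvkit_invalid_argument",
              paste("missing columns:", paste(miss, collapse = ", ")))
  if (any(as.matrix(rows[prv_indicator_names]) < 0))
    prv_error("prvkit_invalid_argument", "MAPE entries must be >= 0")
  structure(rows,
            column_means = colMeans(rows[prv_indicator_names]),
            class = c("mape_table", "data.frame"))
}

#' Column means of a MAPE table
#'
#' @param table a `mape_table`.
#' @return named numeric vector of per-indicator mean MAPE across subjects.
#' @export
column_means <- function(table) {
  stopifnot(inherits(table, "mape_table"))
  attr(table, "column_means")
}

#' @export
print.mape_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  cm <- column_means(x)
  cat("mean   ", paste(sprintf("%s=%.3f", names(cm), cm), collapse = "  "), "\n")
  invisible(x)
}

#' Improvement from PPI-based to NNI-based analysis
#'
#' Element-wise difference `table_ppi - table_nni` of the per-subject rows
#' and of the column means. Positive entries mean the NNI normalization
#' reduced the error for that subject/indicator.
#'
#' @param table_ppi,table_nni congruent `mape_table`s (same subjects).
#' @return list with `rows` (data frame of per-subject deltas) and
#'   `column_means` (named numeric).
#' @export
improvement_delta <- function(table_ppi, table_nni) {
  stopifnot(inherits(table_ppi, "mape_table"), inherits(table_nni, "mape_table"))
  if (!identical(table_ppi$subject, table_nni$subject))
    prv_error("prvkit_invalid_argument", "tables cover different subjects")
  rows <- table_ppi
  rows[prv_indicator_names] <-
    as.data.frame(as.matrix(table_ppi[prv_indicator_names]) -
                    as.matrix(table_nni[prv_indicator_names]))
  list(rows = as.data.frame(rows),
       column_means = column_means(table_ppi) - column_means(table_nni))
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with the validation the agreement analysis needs:
#' at least 3 paired points and nonzero variance in both series. Applied to
#' pooled NNI pairs per subject and to pooled per-segment indicator pairs
#' per indicator.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    prv_error("prvkit_invalid_argument", "need equal-length series of length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    prv_error("prvkit_degenerate_signal", "correlation undefined for constant series")
  cor(x, y)
}

#' Score agreement between reference and test pipeline runs
#'
#' The full comparison for one or more paired recordings: per-segment PRV
#' indicators are computed from the raw intervals (PPI) and from the
#' normalized intervals (NNI) on both channels; MAPE tables are built for
#' each basis; their difference quantifies what the NNI normalization buys;
#' and two correlation views are reported — pooled NNI pairs per subject
#' (beats paired by index after truncation to the shorter series) and
#' pooled per-segment indicator pairs per indicator (NNI basis).
#'
#' @param ref,test named lists of [run_ppi_pipeline()] outputs, one element
#'   per subject (names are subject ids; a single unnamed element is
#'   subject "1").
#' @param bands a [band_definition()].
#' @param cfg a [spectral_config()].
#' @return a `prv_agreement_report` list: `mape_ppi`, `mape_nni`
#'   (`mape_table`s), `delta` (see [improvement_delta()]), `nni_correlation`
#'   (per subject + `average`), `indicator_correlation` (per indicator).
#' @export
agreement_report <- function(ref, test, bands = band_definition(),
                             cfg = spectral_config()) {
  if (inherits(ref[[1]], "ppi_series") || !is.null(ref[[1]]$ppi))
    ref <- list(`1` = ref)  # single subject passed bare
  if (inherits(test[[1]], "ppi_series") || !is.null(test[[1]]$ppi))
    test <- list(`1` = test)
  if (is.null(names(ref))) names(ref) <- seq_along(ref)
  if (is.null(names(test))) names(test) <- seq_along(test)
  if (!identical(sort(names(ref)), sort(names(test))))
    prv_error("prvkit_invalid_argument", "reference and test subjects differ")

  gather <- function(runs, use) {
    do.call(rbind, lapply(names(runs), function(s) {
      df <- segment_indicators(runs[[s]], use = use, bands = bands, cfg = cfg)
      cbind(subject = s, df)
    }))
  }
  ref_ppi <- gather(ref, "ppi"); test_ppi <- gather(test, "ppi")
  ref_nni <- gather(ref, "nni"); test_nni <- gather(test, "nni")

  t_ppi <- build_mape_table(ref_ppi, test_ppi)
  t_nni <- build_mape_table(ref_nni, test_nni)

  nni_cor <- vapply(names(ref), function(s) {
    # pool NNI pairs across segments, pairing beats by index after
    # truncating each segment pair to the shorter series
    pairs <- lapply(seq_along(ref[[s]]), function(i) {
      r <- ref[[s]][[i]]$nni$intervals_ms
      t <- test[[s]][[i]]$nni$intervals_ms
      k <- min(length(r), length(t))
      cbind(r[seq_len(k)], t[seq_len(k)])
    })
    m <- do.call(rbind, pairs)
    pearson_correlation(m[, 1], m[, 2])
  }, numeric(1))

  # with very few segments (or a degenerate spread) the indicator
  # correlation is undefined; report NA rather than abort the whole report
  ind_cor <- vapply(prv_indicator_names, function(ind) {
    tryCatch(pearson_correlation(ref_nni[[ind]], test_nni[[ind]]),
             prvkit_error = function(e) NA_real_)
  }, numeric(1))

  structure(list(
    mape_ppi = t_ppi,
    mape_nni = t_nni,
    delta = improvement_delta(t_ppi, t_nni),
    nni_correlation = c(nni_cor, average = mean(nni_cor)),
    indicator_correlation = ind_cor
  ), class = "prv_agreement_report")
}

#' @export
print.prv_agreement_report <- function(x, ...) {
  cat("== MAPE (%) on raw intervals (PPI basis) ==\n"); print(x$mape_ppi)
  cat("\n== MAPE (%) on normalized intervals (NNI basis) ==\n"); print(x$mape_nni)
  cat("\n== Improvement (PPI - NNI) column means ==\n")
  print(round(x$delta$column_means, 3))
  cat("\nNNI correlation: ",
      paste(sprintf("%s=%.3f", names(x$nni_correlation), x$nni_correlation),
            collapse = "  "), "\n")
  cat("Indicator correlation (NNI basis): ",
      paste(sprintf("%s=%.3f", names(x$indicator_correlation),
                    x$indicator_correlation), collapse = "  "), "\n")
  invisible(x)
}

#' Published per-subject MAPE benchmark tables
#'
#' Transcription of a published 10-subject benchmark comparing PRV
#' indicators from a contact sensor against a 30 Hz camera channel: one
#' table of per-subject MAPE values computed on raw intervals (PPI) and one
#' after z-score normalization (NNI). The raw subject recordings behind
#' these numbers are not publicly shareable; the tables serve as the fixed
#' reference for the aggregation arithmetic (column means and improvement
#' deltas).
#'
#' @return `list(ppi = mape_table, nni = mape_table)`.
#' @export
published_mape_tables <- function() {
  read_one <- function(name) {
    path <- system.file("extdata", name, package = "prvkit", mustWork = TRUE)
    mape_table(read.csv(path))
  }
  list(ppi = read_one("published_mape_ppi.csv"),
       nni = read_one("published_mape_nni.csv"))
}
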