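#' Preprocessing configuration
#'
#' @param trim_seconds Seconds removed from the start of every recording to
#'   cut out the notification vibration (default 0.5).
#' @param split_long Whether 20-second recordings are split into two 10-second
#'   halves (default `TRUE`).
#' @param removed_steps Step names dropped before feature extraction
#'   (default [default_removed_steps()]).
#' @param trend_lambda Regularisation weight of the l1 trend filter used for
#'   degravitation; `>= 0`. The default `1e4` puts the trend's effective
#'   cutoff well below the tremor band (< 1 Hz) on 10-s, 100-Hz, g-scaled
#'   channels.
#' @param degravitate_sensors Sensors whose channels are degravitated
#'   (default acceleration only; rotation rate carries no gravity offset).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(trim_seconds = 0.5, split_long = TRUE,
                              removed_steps = default_removed_steps(),
                              trend_lambda = 1e4,
                              degravitate_sensors = "acceleration") {
  assert_number(trim_seconds, "trim_seconds", lower = 0)
  assert_number(trend_lambda, "trend_lambda", lower = 0)
  assert_flag(split_long, "split_long")
  structure(list(trim_seconds = trim_seconds, split_long = split_long,
                 removed_steps = removed_steps, trend_lambda = trend_lambda,
                 degravitate_sensors = degravitate_sensors),
            class = "preprocess_config")
}

#' Remove the onset vibration window from a series
#'
#' Drops the first `round(trim_seconds * fs)` samples (per axis for matrix
#' input).
#'
#' @param series Numeric vector, or matrix with one column per axis.
#' @param fs Sampling rate in Hz.
#' @param trim_seconds Seconds to remove from the start.
#' @return The trimmed series.
#' @export
trim_onset <- function(series, fs, trim_seconds = 0.5) {
  k <- round(trim_seconds * fs)
  n <- if (is.matrix(series)) nrow(series) else length(series)
  if (n <= k)
    stop("series (", n, " samples) is not longer than the trim window (",
         k, " samples)", call. = FALSE)
  if (k == 0L) return(series)
  if (is.matrix(series)) series[-seq_len(k), , drop = FALSE]
  else series[-seq_len(k)]
}

#' Split a 20-second recording into two 10-second halves
#'
#' Recordings of (approximately) twice the 10-second base duration are cut at
#' the midpoint into two consecutive halves named `<step>_1` and `<step>_2`;
#' 10-second recordings pass through unchanged. Durations are matched with a
#' one-second slack so onset-trimmed recordings (19.5 s / 9.5 s) are handled.
#'
#' @param recording An `assessment_recording`.
#' @param base_duration Base segment duration in seconds (default 10).
#' @return List of one or two `assessment_recording` objects.
#' @export
split_long <- function(recording, base_duration = 10) {
  stopifnot(inherits(recording, "assessment_recording"))
  dur <- nrow(recording$samples) / recording$fs
  if (abs(dur - 2 * base_duration) <= 1) {
    h <- nrow(recording$samples) %/% 2L
    first <- new_recording(paste0(recording$step, "_1"), recording$wrist,
                           recording$sensor,
                           recording$samples[seq_len(h), , drop = FALSE],
                           recording$fs)
    second <- new_recording(paste0(recording$step, "_2"), recording$wrist,
                            recording$sensor,
                            recording$samples[h + seq_len(h), , drop = FALSE],
                            recording$fs)
    list(first, second)
  } else if (abs(dur - base_duration) <= 1) {
    list(recording)
  } else {
    stop("unsupported recording duration: ", dur, " s", call. = FALSE)
  }
}

#' l1 trend filtering
#'
#' Computes the piecewise-linear trend `z` minimising
#' \deqn{\tfrac12 \sum_t (x_t - z_t)^2 + \lambda \sum_t |z_{t-1} - 2 z_t + z_{t+1}|,}
#' i.e. a least-squares fit with an l1 penalty on second differences. The
#' convex problem is solved exactly through its dual box-constrained QP with a
#' primal-dual interior-point method whose Newton systems are pentadiagonal
#' (banded LDL factorisation, O(n) per iteration); matrix input is filtered
#' column-wise.
#'
#' @param series Numeric vector (length `>= 3`) or matrix with one series per
#'   column.
#' @param lambda Regularisation weight `>= 0`; `0` returns the input exactly.
#' @param max_iter Maximum interior-point iterations.
#' @param tol Relative duality-gap tolerance.
#' @return The trend, same shape as the input.
#' @export
l1_trend_filter <- function(series, lambda, max_iter = 60L, tol = 1e-10) {
  assert_number(lambda, "lambda", lower = 0)
  x <- if (is.matrix(series)) series else matrix(series, ncol = 1L)
  if (any(!is.finite(x))) stop("series contains non-finite samples",
                               call. = FALSE)
  if (nrow(x) < 3L) stop("series must have at least 3 samples", call. = FALSE)
  if (lambda == 0) return(series)
  z <- .l1tf_cpp(x, lambda, tol, as.integer(max_iter))
  if (is.matrix(series)) z else drop(z)
}

# Objective of the l1 trend filtering problem; used by tests and diagnostics.
l1_trend_objective <- function(x, z, lambda) {
  d2 <- diff(z, differences = 2L)
  0.5 * sum((x - z)^2) + lambda * sum(abs(d2))
}

#' Remove the gravitational trend from a series
#'
#' Subtracts the l1-trend-filter estimate of the slow gravitational
#' orientation component, leaving zero-mean physiological signal. The
#' decomposition is exact: `degravitate(x) + l1_trend_filter(x) == x`.
#'
#' @inheritParams l1_trend_filter
#' @return The detrended series, same shape as the input.
#' @export
degravitate <- function(series, lambda, ...) {
  series - l1_trend_filter(series, lambda, ...)
}

#' Preprocess a session into uniform 10-second segments
#'
#' Applies the preprocessing pipeline in order: drop removed steps, trim the
#' onset vibration window, split 20-second recordings in half, truncate all
#' segments to the shortest common length, and degravitate the selected
#' sensors' channels (all axes of one subject are filtered in a single
#' batched ADMM run).
#'
#' @param session An `assessment_session`.
#' @param config A [preprocess_config()].
#' @param protocol Protocol used to label each segment with its task category.
#' @return Named list of segment `assessment_recording`s (segment name in
#'   `$step`, task category in the `"category"` attribute), all of equal
#'   length, ready for [assemble_channels()].
#' @export
preprocess_session <- function(session, config = preprocess_config(),
                               protocol = default_protocol()) {
  stopifnot(inherits(session, "assessment_session"))
  categories <- stats::setNames(protocol$category, protocol$step)
  rec_keys <- vapply(session$recordings, function(r)
    paste(r$step, r$wrist, r$sensor, sep = "_"), character(1))
  names(session$recordings) <- rec_keys
  # iterate in protocol order so the segment (and hence channel) ordering is
  # a pure function of the protocol, not of file-system enumeration
  steps <- intersect(protocol$step,
                     unique(vapply(session$recordings, `[[`, "", "step")))
  segs <- list()
  for (step in setdiff(steps, config$removed_steps)) {
    for (wrist in .wrists) for (sensor in .sensors) {
      rec <- session$recordings[[paste(step, wrist, sensor, sep = "_")]]
      if (is.null(rec)) next
      trimmed <- rec
      trimmed$samples <- trim_onset(rec$samples, rec$fs, config$trim_seconds)
      parts <- if (config$split_long) split_long(trimmed) else list(trimmed)
      for (p in parts) {
        base_step <- sub("_[12]$", "", p$step)
        attr(p, "category") <- unname(categories[base_step])
        if (is.na(attr(p, "category")))
          attr(p, "category") <- "Resting"
        segs[[paste(p$step, p$wrist, p$sensor, sep = "_")]] <- p
      }
    }
  }
  if (!length(segs)) return(segs)

  n_min <- min(vapply(segs, function(r) nrow(r$samples), integer(1)))
  segs <- lapply(segs, function(r) {
    r$samples <- r$samples[seq_len(n_min), , drop = FALSE]
    r
  })

  if (config$trend_lambda > 0 && length(config$degravitate_sensors)) {
    target <- vapply(segs, function(r)
      r$sensor %in% config$degravitate_sensors, logical(1))
    if (any(target) && n_min >= 3L) {
      block <- do.call(cbind, lapply(segs[target], function(r) r$samples))
      trend <- l1_trend_filter(block, config$trend_lambda)
      resid <- block - trend
      j <- 0L
      for (key in names(segs)[target]) {
        segs[[key]]$samples <- resid[, j + 1:3, drop = FALSE]
        colnames(segs[[key]]$samples) <- .axes
        j <- j + 3L
      }
    }
  }
  segs
}
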