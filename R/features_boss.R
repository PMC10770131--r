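#' Configuration of the symbolic Fourier approximation (SFA)
#'
#' SFA converts each sliding window of a series into a short discrete word:
#' the window is (optionally z-normalised and) Fourier-transformed, the first
#' `word_length` low-frequency coefficient values (real and imaginary parts
#' interleaved) are kept, and each value is quantised into `alphabet_size`
#' bins fitted on training data (multiple coefficient binning). With
#' normalisation on, the DC coefficient is dropped (offset invariance); with
#' normalisation off it is kept.
#'
#' @param window_length Sliding-window length in samples.
#' @param word_length Number of quantised coefficient values per word
#'   (default 4).
#' @param alphabet_size Number of quantisation bins per value (default 4).
#' @param normalize_windows Z-normalise each window before the DFT
#'   (default `TRUE`, as in the original bag-of-SFA-symbols formulation).
#' @param numerosity_reduction Count runs of consecutive identical words once
#'   (default `TRUE`).
#' @param binning `"equi-depth"` (training quantiles) or `"equi-width"`.
#' @return An object of class `sfa_config`.
#' @export
sfa_config <- function(window_length, word_length = 4, alphabet_size = 4,
                       normalize_windows = TRUE, numerosity_reduction = TRUE,
                       binning = "equi-depth") {
  binning <- match.arg(binning, c("equi-depth", "equi-width"))
  if (word_length > window_length)
    stop("word_length must not exceed window_length", call. = FALSE)
  if (alphabet_size < 2) stop("alphabet_size must be >= 2", call. = FALSE)
  assert_flag(normalize_windows, "normalize_windows")
  assert_flag(numerosity_reduction, "numerosity_reduction")
  structure(list(window_length = as.integer(window_length),
                 word_length = as.integer(word_length),
                 alphabet_size = as.integer(alphabet_size),
                 normalize_windows = normalize_windows,
                 numerosity_reduction = numerosity_reduction,
                 binning = binning),
            class = "sfa_config")
}

# n_win x window_length matrix of stride-1 sliding windows
sliding_windows <- function(series, window_length) {
  n <- length(series)
  if (window_length > n)
    stop("window (", window_length, ") longer than series (", n, ")",
         call. = FALSE)
  n_win <- n - window_length + 1L
  idx <- outer(seq_len(n_win), 0:(window_length - 1L), `+`)
  matrix(series[idx], nrow = n_win)
}

# Real-valued DFT coefficient values of each window, in SFA order:
# with the DC term, [Re c0, Re c1, Im c1, Re c2, ...]; without it,
# [Re c1, Im c1, Re c2, Im c2, ...]. Returns n_win x word_length matrix.
sfa_coefficients <- function(series, config) {
  W <- sliding_windows(series, config$window_length)
  if (config$normalize_windows) {
    mu <- rowMeans(W)
    W <- W - mu
    sdv <- sqrt(rowMeans(W^2))
    W <- W / pmax(sdv, 1e-12)
  }
  L <- config$window_length
  t <- 0:(L - 1L)
  drop_dc <- config$normalize_windows
  vals <- matrix(0, nrow(W), config$word_length)
  col <- 0L; k <- if (drop_dc) 1L else 0L
  take_re <- TRUE
  while (col < config$word_length) {
    col <- col + 1L
    if (k == 0L) {
      vals[, col] <- rowSums(W)           # Re(c0); Im(c0) = 0, skipped
      k <- 1L; take_re <- TRUE
    } else if (take_re) {
      vals[, col] <- W %*% cos(2 * pi * k * t / L)
      take_re <- FALSE
    } else {
      vals[, col] <- W %*% (-sin(2 * pi * k * t / L))
      take_re <- TRUE; k <- k + 1L
    }
  }
  vals
}

#' Fit SFA quantisation bins on training series
#'
#' Multiple coefficient binning: per coefficient value, `alphabet_size - 1`
#' breakpoints are derived from the pooled training windows (quantiles for
#' equi-depth, an even grid for equi-width). Bins must be fitted on training
#' data only; the fitted object is then applied unchanged to test series.
#'
#' @param series_list List of numeric vectors (training series).
#' @param config An [sfa_config()].
#' @return An object of class `sfa_bins` (breakpoint matrix
#'   `word_length x (alphabet_size - 1)` plus the config).
#' @export
sfa_fit_bins <- function(series_list, config) {
  if (!is.list(series_list)) series_list <- list(series_list)
  vals <- do.call(rbind, lapply(series_list, sfa_coefficients,
                                config = config))
  a <- config$alphabet_size
  breaks <- matrix(0, config$word_length, a - 1L)
  for (j in seq_len(config$word_length)) {
    v <- vals[, j]
    breaks[j, ] <- if (config$binning == "equi-depth")
      stats::quantile(v, probs = seq_len(a - 1L) / a, names = FALSE,
                      type = 7)
    else
      min(v) + diff(range(v)) * seq_len(a - 1L) / a
  }
  structure(list(breaks = breaks, config = config), class = "sfa_bins")
}

#' Transform a series into its SFA word sequence
#'
#' Each stride-1 sliding window becomes one word: its coefficient values are
#' quantised through the fitted breakpoints into symbols `0..alphabet_size-1`
#' and packed into a single integer (first symbol most significant). The
#' number of words is `length(series) - window_length + 1`.
#'
#' @param series Numeric vector.
#' @param fitted_bins An `sfa_bins` object from [sfa_fit_bins()].
#' @return Integer vector of words in `0..alphabet_size^word_length - 1`.
#' @export
sfa_transform <- function(series, fitted_bins) {
  stopifnot(inherits(fitted_bins, "sfa_bins"))
  config <- fitted_bins$config
  vals <- sfa_coefficients(series, config)
  a <- config$alphabet_size
  words <- integer(nrow(vals))
  for (j in seq_len(config$word_length)) {
    sym <- findInterval(vals[, j], fitted_bins$breaks[j, ])
    words <- words * a + sym
  }
  words
}

#' Word histogram with optional numerosity reduction
#'
#' Counts word occurrences over the full vocabulary of
#' `alphabet_size^word_length` words. With numerosity reduction, runs of
#' consecutive identical words contribute one count (suppressing
#' over-counting of slowly varying stretches).
#'
#' @param words Integer word sequence from [sfa_transform()].
#' @param config The [sfa_config()] used to produce the words.
#' @return Named integer vector of length `alphabet_size^word_length`.
#' @export
boss_histogram <- function(words, config) {
  if (config$numerosity_reduction && length(words) > 1L)
    words <- words[c(TRUE, words[-1L] != words[-length(words)])]
  vocab <- config$alphabet_size^config$word_length
  counts <- tabulate(words + 1L, nbins = vocab)
  names(counts) <- paste0("w", seq_len(vocab) - 1L)
  counts
}

#' Fit multi-scale BOSS transformers on training tensors
#'
#' Fits one SFA quantisation per (channel x window length), pooling the
#' training subjects' series of that channel, for the hierarchical window
#' sizes (20, 40 and 80 samples by default) that capture signal substructure
#' at different scales.
#'
#' @param tensors List of training `channel_tensor`s (equal channel layout).
#' @param windows Integer vector of sliding-window lengths in samples.
#' @param word_length,alphabet_size,normalize_windows,numerosity_reduction,binning
#'   Passed to [sfa_config()].
#' @return An object of class `boss_fit` holding the per-channel, per-window
#'   fitted bins and the channel annotations.
#' @export
boss_cohort_fit <- function(tensors, windows = c(20, 40, 80),
                            word_length = 4, alphabet_size = 4,
                            normalize_windows = TRUE,
                            numerosity_reduction = TRUE,
                            binning = "equi-depth") {
  info <- tensors[[1]]$info
  fits <- vector("list", nrow(info))
  for (ch in seq_len(nrow(info))) {
    series_list <- lapply(tensors, function(tn) tn$channels[, ch])
    fits[[ch]] <- lapply(windows, function(wl)
      sfa_fit_bins(series_list,
                   sfa_config(wl, word_length, alphabet_size,
                              normalize_windows, numerosity_reduction,
                              binning)))
  }
  structure(list(fits = fits, windows = windows, info = info),
            class = "boss_fit")
}

#' BOSS feature row for one subject's channel tensor
#'
#' Transforms every channel at every fitted window scale into a fixed-length
#' word histogram and concatenates them in deterministic channel-major,
#' window-minor order. Columns are annotated with the channel's task category
#' for grouped importance analysis.
#'
#' @param fit A `boss_fit` from [boss_cohort_fit()].
#' @param tensor A `channel_tensor` with the same channel layout.
#' @return Numeric vector with a `"col_info"` attribute (data frame:
#'   `channel`, `window`, `feature`, `category`, `sensor`).
#' @export
featurize_boss <- function(fit, tensor) {
  stopifnot(inherits(fit, "boss_fit"), inherits(tensor, "channel_tensor"))
  if (nrow(tensor$info) != nrow(fit$info))
    stop("tensor channel layout does not match the fitted transformer",
         call. = FALSE)
  blocks <- list(); infos <- list()
  for (ch in seq_len(nrow(fit$info))) {
    series <- tensor$channels[, ch]
    for (w in seq_along(fit$windows)) {
      bins <- fit$fits[[ch]][[w]]
      h <- boss_histogram(sfa_transform(series, bins), bins$config)
      key <- paste0(fit$info$label[ch], ".w", fit$windows[w])
      names(h) <- paste0(key, ".", names(h))
      blocks[[key]] <- h
      infos[[key]] <- data.frame(
        channel = fit$info$label[ch], window = fit$windows[w],
        feature = names(h), category = fit$info$category[ch],
        sensor = fit$info$sensor[ch], stringsAsFactors = FALSE)
    }
  }
  values <- unlist(blocks, use.names = FALSE)
  col_info <- do.call(rbind, c(infos, make.row.names = FALSE))
  names(values) <- col_info$feature
  attr(values, "col_info") <- col_info
  values
}
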