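#' Configuration for the manual spectral/statistical features
#'
#' @param fs Sampling rate in Hz.
#' @param freq_step Frequency resolution of the Welch estimate in Hz
#'   (default 1; achieved exactly with `fs`-sample sub-windows).
#' @param f_min,f_max Lowest/highest retained frequency bin in Hz (defaults
#'   1 and 19: the 0 Hz bin and everything above 19 Hz are discarded).
#' @param n_segments Number of equal-length segments for the time-domain
#'   statistics (default 4).
#' @param log_floor Additive floor inside the log scaling of spectral power,
#'   guarding zero-power bins.
#' @param energy Either `"squared"` (sum of squares, the conventional
#'   absolute-energy statistic) or `"absolute"` (sum of absolute values).
#' @return An object of class `manual_feature_config`.
#' @export
manual_feature_config <- function(fs = 100, freq_step = 1, f_min = 1,
                                  f_max = 19, n_segments = 4,
                                  log_floor = 1e-12, energy = "squared") {
  energy <- match.arg(energy, c("squared", "absolute"))
  if (f_min < freq_step) stop("f_min must be >= freq_step", call. = FALSE)
  if (f_max >= fs / 2) stop("f_max must be below the Nyquist frequency",
                            call. = FALSE)
  if (n_segments < 1) stop("n_segments must be >= 1", call. = FALSE)
  assert_number(log_floor, "log_floor", lower = 0)
  structure(list(fs = fs, freq_step = freq_step, f_min = f_min, f_max = f_max,
                 n_segments = n_segments, log_floor = log_floor,
                 energy = energy),
            class = "manual_feature_config")
}

#' Welch power spectral density estimate
#'
#' Averages modified periodograms of Hann-windowed sub-windows with 50%
#' overlap. With `window_samples = fs` (the default) the frequency grid is
#' exactly 1 Hz.
#'
#' @param channel Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param window_samples Sub-window length in samples.
#' @param overlap Fractional overlap between consecutive sub-windows.
#' @return List with `freq` (Hz) and `psd` (one-sided density) vectors.
#' @export
welch_psd <- function(channel, fs, window_samples = fs, overlap = 0.5) {
  n <- length(channel)
  win <- round(window_samples)
  if (n < win)
    stop("channel (", n, " samples) shorter than one Welch window (",
         win, ")", call. = FALSE)
  hop <- max(1L, round(win * (1 - overlap)))
  starts <- seq(1L, n - win + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / win)  # Hann (periodic)
  U <- sum(w^2)
  nf <- win %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- channel[s:(s + win - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / (fs * U)
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided scaling: double everything except DC (and Nyquist if present)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (win %% 2L == 0L) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / win, psd = psd * dbl)
}

#' Log-scaled Welch PSD features of one channel
#'
#' Estimates the PSD in discrete `freq_step` Hz steps, discards the 0 Hz bin
#' and everything above `f_max` Hz, and log-scales the retained bins
#' (natural log with an additive floor). With the defaults this yields the
#' 19 spectral features per channel.
#'
#' @param channel Numeric vector (one 10-s single-axis series).
#' @param config A [manual_feature_config()].
#' @return Named numeric vector of `(f_max - f_min)/freq_step + 1` features
#'   in ascending frequency order.
#' @export
psd_features <- function(channel, config = manual_feature_config()) {
  win <- round(config$fs / config$freq_step)
  est <- welch_psd(channel, config$fs, window_samples = win)
  keep <- seq(config$f_min, config$f_max, by = config$freq_step)
  idx <- match(keep, round(est$freq, 9))
  vals <- log(est$psd[idx] + config$log_floor)
  names(vals) <- sprintf("psd_%ghz", keep)
  vals
}

#' Per-segment time-domain statistics of one channel
#'
#' Cuts the channel into `n_segments` equal-length contiguous segments
#' (remainder samples dropped from the tail) and computes, per segment, the
#' standard deviation, the maximum absolute amplitude and the sum of absolute
#' energy, in that order.
#'
#' @inheritParams psd_features
#' @return Named numeric vector of `3 * n_segments` features.
#' @export
segment_features <- function(channel, config = manual_feature_config()) {
  k <- config$n_segments
  n <- length(channel)
  if (n < k) stop("channel (", n, " samples) shorter than n_segments (", k,
                  ")", call. = FALSE)
  len <- n %/% k
  out <- numeric(3L * k)
  nms <- character(3L * k)
  for (i in seq_len(k)) {
    seg <- channel[((i - 1L) * len + 1L):(i * len)]
    m <- mean(seg)
    out[3L * i - 2L] <- sqrt(mean((seg - m)^2))
    out[3L * i - 1L] <- max(abs(seg))
    out[3L * i] <- if (config$energy == "squared") sum(seg^2) else
      sum(abs(seg))
    nms[(3L * i - 2L):(3L * i)] <- paste0("seg", i, c("_sd", "_absmax",
                                                      "_energy"))
  }
  stats::setNames(out, nms)
}

#' Full manual feature vector of one channel
#'
#' Concatenation of [psd_features()] and [segment_features()]; 31 features
#' with the default configuration (19 spectral + 12 segment statistics).
#'
#' @inheritParams psd_features
#' @return Named numeric vector.
#' @export
channel_features <- function(channel, config = manual_feature_config()) {
  c(psd_features(channel, config), segment_features(channel, config))
}

#' Manual feature row for one subject's channel tensor
#'
#' Applies [channel_features()] to every channel and concatenates the results
#' channel-major. Column annotations carry the channel label, feature name
#' and the channel's task category, enabling grouped importance analysis.
#'
#' @param tensor A `channel_tensor` (see [assemble_channels()]).
#' @param config A [manual_feature_config()].
#' @return Numeric vector of `31 * n_channels` values with a `"col_info"`
#'   attribute (data frame: `channel`, `feature`, `category`).
#' @export
featurize_manual <- function(tensor, config = manual_feature_config()) {
  stopifnot(inherits(tensor, "channel_tensor"))
  per_channel <- lapply(seq_len(ncol(tensor$channels)), function(j)
    channel_features(tensor$channels[, j], config))
  p <- length(per_channel[[1]])
  values <- unlist(per_channel, use.names = FALSE)
  feature_names <- names(per_channel[[1]])
  col_info <- data.frame(
    channel = rep(tensor$info$label, each = p),
    feature = rep(feature_names, times = ncol(tensor$channels)),
    category = rep(tensor$info$category, each = p),
    sensor = rep(tensor$info$sensor, each = p),
    stringsAsFactors = FALSE
  )
  names(values) <- paste(col_info$channel, col_info$feature, sep = ".")
  attr(values, "col_info") <- col_info
  values
}
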