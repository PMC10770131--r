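# Brute-force SFA oracle: explicit per-window DFT, explicit quantile
# breakpoints, explicit symbol packing. Mirrors the documented contract, not
# the package implementation.
oracle_sfa_values <- function(series, window, word, normalize) {
  n_win <- length(series) - window + 1
  vals <- matrix(0, n_win, word)
  for (w in seq_len(n_win)) {
    win <- series[w:(w + window - 1)]
    if (normalize) {
      win <- win - mean(win)
      win <- win / max(sqrt(mean(win^2)), 1e-12)
    }
    co <- stats::fft(win)                  # c_k = sum x_t exp(-2pi i k t / L)
    seq_vals <- c()
    k <- if (normalize) 1 else 0           # drop DC iff normalised
    while (length(seq_vals) < word) {
      if (k == 0) {
        seq_vals <- c(seq_vals, Re(co[1]))
      } else {
        seq_vals <- c(seq_vals, Re(co[k + 1]), Im(co[k + 1]))
      }
      k <- k + 1
    }
    vals[w, ] <- seq_vals[seq_len(word)]
  }
  vals
}

oracle_sfa_words <- function(train_list, series, window, word, alphabet,
                             normalize) {
  pooled <- do.call(rbind, lapply(train_list, oracle_sfa_values,
                                  window = window, word = word,
                                  normalize = normalize))
  breaks <- apply(pooled, 2, stats::quantile,
                  probs = seq_len(alphabet - 1) / alphabet, type = 7,
                  names = FALSE)
  breaks <- matrix(breaks, nrow = alphabet - 1)
  vals <- oracle_sfa_values(series, window, word, normalize)
  words <- integer(nrow(vals))
  for (j in seq_len(word)) {
    sym <- vapply(vals[, j], function(v) sum(breaks[, j] <= v), numeric(1))
    words <- words * alphabet + as.integer(sym)
  }
  words
}
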