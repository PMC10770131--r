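test_that("sfa_config validates its arguments", {
  expect_error(sfa_config(4, word_length = 8), "word_length")
  expect_error(sfa_config(8, alphabet_size = 1), "alphabet_size")
  expect_error(sfa_config(8, normalize_windows = "yes"), "TRUE or FALSE")
})

test_that("word counts and degenerate series behave as specified", {
  set.seed(12)
  x <- rnorm(100)
  cfg <- sfa_config(20)
  bins <- sfa_fit_bins(list(x), cfg)
  expect_length(sfa_transform(x, bins), 81)
  expect_error(sfa_transform(rnorm(10), bins), "longer than series")

  const <- rep(1, 60)
  cbins <- sfa_fit_bins(list(const), sfa_config(20, normalize_windows = FALSE))
  words <- sfa_transform(const, cbins)
  expect_length(unique(words), 1)          # identical windows, identical words
})

test_that("boss_histogram implements run-length numerosity reduction", {
  cfg_on <- sfa_config(8, word_length = 2, alphabet_size = 2)
  cfg_off <- sfa_config(8, word_length = 2, alphabet_size = 2,
                        numerosity_reduction = FALSE)
  const_words <- rep(3L, 41)
  h_on <- boss_histogram(const_words, cfg_on)
  h_off <- boss_histogram(const_words, cfg_off)
  expect_equal(unname(h_on["w3"]), 1)
  expect_equal(unname(h_off["w3"]), 41)
  expect_equal(sum(h_on), 1)
  expect_equal(sum(h_off), 41)

  # [A, A, B, A] -> {A: 2, B: 1}
  h <- boss_histogram(c(0L, 0L, 1L, 0L), cfg_on)
  expect_equal(unname(h["w0"]), 2)
  expect_equal(unname(h["w1"]), 1)
})

test_that("SFA agrees with the explicit-DFT oracle on small toys", {
  set.seed(13)
  for (normalize in c(TRUE, FALSE)) {
    for (rep_i in 1:5) {
      train <- lapply(1:3, function(i) rnorm(32))
      x <- rnorm(32)
      cfg <- sfa_config(8, word_length = 2, alphabet_size = 2,
                        normalize_windows = normalize)
      bins <- sfa_fit_bins(train, cfg)
      got <- sfa_transform(x, bins)
      want <- oracle_sfa_words(train, x, 8, 2, 2, normalize)
      expect_equal(got, want)
    }
  }
  # a wider configuration on a 16-point toy
  train <- lapply(1:2, function(i) rnorm(16))
  x <- rnorm(16)
  cfg <- sfa_config(8, word_length = 4, alphabet_size = 4)
  bins <- sfa_fit_bins(train, cfg)
  expect_equal(sfa_transform(x, bins),
               oracle_sfa_words(train, x, 8, 4, 4, TRUE))
})

test_that("featurize_boss concatenates fixed-vocabulary histograms", {
  set.seed(14)
  ch <- matrix(rnorm(200 * 2), ncol = 2)
  ch[, 2] <- ch[, 1]                       # two identical channels
  info <- data.frame(segment = "s", arm = c("left", "right"),
                     sensor = "acceleration", axis = "x",
                     category = c("Resting", "Postural"),
                     label = c("c1", "c2"), stringsAsFactors = FALSE)
  tensor <- structure(list(subject_id = "a", channels = ch, info = info),
                      class = "channel_tensor")
  fit <- boss_cohort_fit(list(tensor), windows = c(20, 40, 80))
  row <- featurize_boss(fit, tensor)
  expect_length(row, 2 * 3 * 256)          # channels x windows x 4^4
  ci <- attr(row, "col_info")
  expect_equal(nrow(ci), length(row))
  expect_equal(unname(row[1:768]), unname(row[769:1536]))  # identical blocks
  # histogram totals bounded by the window count
  n_win <- nrow(ch) - 20 + 1
  expect_true(all(tapply(row, paste(ci$channel, ci$window), sum) <= n_win))
})

test_that("histograms are invariant to a one-period circular shift", {
  # tile one sampled period so the shifted copy repeats the same floating-
  # point values (sin(t) and sin(t + 2*pi) differ by an ulp otherwise)
  x <- rep(sin(2 * pi * (0:19) / 20), 10)  # period 20 samples, length 200
  shifted <- c(x[21:200], x[1:20])
  cfg <- sfa_config(20, numerosity_reduction = FALSE)
  bins <- sfa_fit_bins(list(x), cfg)
  h1 <- boss_histogram(sfa_transform(x, bins), cfg)
  h2 <- boss_histogram(sfa_transform(shifted, bins), cfg)
  expect_equal(h1, h2)
})

test_that("bins are deterministic and respond to different training folds", {
  set.seed(15)
  fold_a <- lapply(1:3, function(i) rnorm(100))
  fold_b <- lapply(1:3, function(i) rnorm(100, mean = 5))
  cfg <- sfa_config(20, normalize_windows = FALSE)
  expect_identical(sfa_fit_bins(fold_a, cfg), sfa_fit_bins(fold_a, cfg))
  expect_false(isTRUE(all.equal(sfa_fit_bins(fold_a, cfg)$breaks,
                                sfa_fit_bins(fold_b, cfg)$breaks)))
  x <- rnorm(100)
  bins <- sfa_fit_bins(fold_a, cfg)
  expect_identical(sfa_transform(x, bins), sfa_transform(x, bins))
})

test_that("equi-width binning uses an even grid over the training range", {
  train <- list(seq(0, 1, length.out = 50))
  cfg <- sfa_config(10, word_length = 2, alphabet_size = 4,
                    normalize_windows = FALSE, binning = "equi-width")
  bins <- sfa_fit_bins(train, cfg)
  vals <- watchpd:::sfa_coefficients(train[[1]], cfg)
  for (j in 1:2) {
    rng <- range(vals[, j])
    expect_equal(bins$breaks[j, ],
                 rng[1] + diff(rng) * (1:3) / 4)
  }
})
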