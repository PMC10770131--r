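test_that("trim_onset drops exactly the onset window", {
  x <- seq_len(1000)
  expect_equal(trim_onset(x, 100, 0.5), x[51:1000])
  expect_length(trim_onset(x, 100, 0.5), 950)
  expect_identical(trim_onset(x, 100, 0), x)
  expect_error(trim_onset(seq_len(40), 100, 0.5), "not longer than")
  m <- matrix(rnorm(300), ncol = 3)
  expect_equal(nrow(trim_onset(m, 100, 0.5)), 50)
})

test_that("split_long halves 20-s recordings at the midpoint", {
  ramp <- matrix(rep(seq_len(2000), 3), ncol = 3)
  rec <- watchpd:::new_recording("relaxed1", "left", "acceleration", ramp, 100)
  parts <- split_long(rec)
  expect_length(parts, 2)
  expect_equal(vapply(parts, `[[`, "", "step"), c("relaxed1_1", "relaxed1_2"))
  expect_equal(nrow(parts[[1]]$samples), 1000)
  # boundary continuity: first half ends where the second begins
  expect_equal(parts[[1]]$samples[1000, 1] + 1, parts[[2]]$samples[1, 1])

  short <- watchpd:::new_recording("touch_nose", "left", "acceleration",
                                   matrix(rnorm(3000), ncol = 3), 100)
  expect_identical(split_long(short), list(short))
  odd <- watchpd:::new_recording("x", "left", "acceleration",
                                 matrix(rnorm(3 * 500), ncol = 3), 100)
  expect_error(split_long(odd), "unsupported recording duration")
})

test_that("the full protocol yields 14 ten-second task segments", {
  segs <- full_segments()
  seg_names <- unique(vapply(segs, `[[`, "", "step"))
  expect_length(seg_names, 14)
  lens <- vapply(segs, function(r) nrow(r$samples), integer(1))
  expect_true(all(lens == lens[1]))          # common truncated length
  expect_equal(unname(lens[1]), 950)         # shortest: 10 s minus 0.5-s trim
})

test_that("default step removal leaves 11 segments (132 channels)", {
  segs <- preprocess_session(full_session(), preprocess_config())
  expect_length(unique(vapply(segs, `[[`, "", "step")), 11)
  expect_equal(ncol(assemble_channels(segs, "s")$channels), 132)
})

test_that("l1 trend filter satisfies its contract on closed-form cases", {
  ramp <- seq(0, 5, length.out = 200)
  expect_equal(l1_trend_filter(ramp, 10), ramp, tolerance = 1e-8)
  x <- rnorm(100)
  expect_identical(l1_trend_filter(x, 0), x)
  expect_error(l1_trend_filter(c(1, NA, 3, 4), 1), "non-finite")
  expect_error(l1_trend_filter(c(1, 2), 1), "at least 3")
  expect_error(l1_trend_filter(x, -1), "lambda must be")
})

test_that("l1 trend filter recovers a known line + sinusoid decomposition", {
  set.seed(41)
  n <- 1000
  t <- seq_len(n)
  line <- 0.01 * t
  sinus <- sin(2 * pi * 4 * (t - 1) / 100)
  x <- line + sinus
  trend <- l1_trend_filter(x, 1e4)
  expect_lt(max(abs(trend - line)), 0.05)
  expect_lt(max(abs((x - trend) - sinus)), 0.1)
})

test_that("degravitation removes drift and preserves the tremor peak", {
  n <- 950
  const <- rep(2.5, n)
  expect_lt(max(abs(degravitate(const, 1e4))), 1e-8)
  drift <- 1 + 0.002 * seq_len(n)
  expect_lt(max(abs(degravitate(drift, 1e4))), 1e-8)

  t <- (seq_len(n) - 1) / 100
  sinus <- 0.05 * sin(2 * pi * 5 * t)
  with_drift <- sinus + drift
  peak_bin <- function(v) {
    est <- welch_psd(v, 100)
    keep <- est$freq >= 1 & est$freq <= 19
    est$freq[keep][which.max(est$psd[keep])]
  }
  expect_equal(peak_bin(degravitate(with_drift, 1e4)), peak_bin(sinus))
})

test_that("trend + residual reconstructs the input to machine precision", {
  set.seed(5)
  x <- cumsum(rnorm(950, 0, 0.01)) + 0.05 * sin(2 * pi * 4 * (1:950) / 100)
  trend <- l1_trend_filter(x, 1e4)
  expect_equal(degravitate(x, 1e4) + trend, x, tolerance = 1e-14)
})

test_that("preprocess_session batches degravitation per sensor selection", {
  s <- generate_cohort(generator_config(n_pd = 1, seed = 31,
                                        protocol = tiny_protocol()))[[1]]
  segs <- preprocess_session(s, preprocess_config(removed_steps = character(0)),
                             tiny_protocol())
  for (r in segs) {
    if (r$sensor == "acceleration")
      expect_lt(max(abs(colMeans(r$samples))), 0.05)  # gravity removed
  }
  raw <- preprocess_session(
    s, preprocess_config(removed_steps = character(0), trend_lambda = 0),
    tiny_protocol())
  acc <- raw[[grep("acceleration", names(raw))[1]]]
  expect_gt(max(abs(colMeans(acc$samples))), 0.1)     # gravity still present
})

test_that("preprocessing is near-idempotent on processed channels", {
  s <- generate_cohort(generator_config(n_pd = 1, seed = 32,
                                        protocol = tiny_protocol()))[[1]]
  cfg1 <- preprocess_config(removed_steps = character(0))
  segs <- preprocess_session(s, cfg1, tiny_protocol())
  # feed the processed segments back through with trim 0 and no splitting
  s2 <- s
  s2$recordings <- segs
  cfg0 <- preprocess_config(trim_seconds = 0, split_long = FALSE,
                            removed_steps = character(0))
  segs2 <- preprocess_session(s2, cfg0, tiny_protocol())
  expect_identical(names(segs2), names(segs))
  for (key in names(segs)) {
    a <- segs[[key]]$samples
    b <- segs2[[key]]$samples
    expect_equal(dim(a), dim(b))
    expect_gt(stats::cor(as.vector(a), as.vector(b)), 0.999)
  }
})
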