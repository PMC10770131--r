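test_that("empty cohort and configuration errors", {
  expect_length(generate_cohort(generator_config(seed = 1)), 0)
  expect_error(generator_config(n_pd = 1, fs = 0), "fs must be")
  expect_error(generator_config(n_pd = -1), "non-negative")
  expect_error(generator_config(n_pd = 1, protocol = data.frame()),
               "non-empty")
})

test_that("identical seeds produce bit-identical cohorts", {
  cfg <- generator_config(n_pd = 1, n_hc = 1, seed = 7,
                          protocol = tiny_protocol())
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(length(a), 2)
})

test_that("a session holds one recording per (step, wrist, sensor)", {
  s <- full_session()
  expect_s3_class(s, "assessment_session")
  expect_length(s$recordings, 11 * 2 * 2)
  durs <- vapply(s$recordings, function(r) nrow(r$samples) / r$fs, numeric(1))
  steps <- vapply(s$recordings, `[[`, "", "step")
  proto <- default_protocol()
  expect_equal(unname(durs),
               unname(proto$duration[match(steps, proto$step)]))
  expect_length(s$questionnaire, 30)
  expect_true(all(s$questionnaire %in% 0:1))
})

test_that("with all stochastic terms off the signal is the constant gravity offset", {
  cfg <- generator_config(seed = 1, gravity_drift_scale = 0, noise_sd = 0,
                          vibration = list(duration = 0, amplitude = 0,
                                           frequency = 25))
  hc <- subject_profile("h1", "HC")
  step <- default_protocol()[3, ]   # 10-s postural step
  set.seed(4)
  x <- generate_signal(hc, step, "right", "acceleration", cfg)
  expect_equal(nrow(x), 1000)
  expect_equal(apply(x, 2, stats::sd), c(x = 0, y = 0, z = 0))
  expect_equal(sqrt(sum(x[1, ]^2)), 1)              # unit gravity magnitude
  set.seed(4)
  r <- generate_signal(hc, step, "right", "rotation", cfg)
  expect_true(all(r == 0))                          # no gravity on gyroscope
})

test_that("PD rest tremor shows a dominant spectral peak at tremor_freq", {
  cfg <- generator_config(seed = 1, gravity_drift_scale = 0, noise_sd = 0.001,
                          vibration = list(duration = 0, amplitude = 0,
                                           frequency = 25))
  pd <- subject_profile("p1", "PD", tremor_freq = 4, tremor_amp = 0.1,
                        laterality = 1, tremor_context = "rest",
                        dominant_side = "right")
  rest <- default_protocol()[1, ]
  set.seed(2)
  x <- generate_signal(pd, rest, "right", "acceleration", cfg)
  axis <- which.max(apply(x, 2, stats::var))
  est <- welch_psd(x[, axis], cfg$fs)
  keep <- est$freq >= 1 & est$freq <= 19
  expect_equal(est$freq[keep][which.max(est$psd[keep])], 4)
})

test_that("tremor gating by laterality and task context", {
  cfg <- generator_config(seed = 1, gravity_drift_scale = 0, noise_sd = 0,
                          vibration = list(duration = 0, amplitude = 0,
                                           frequency = 25))
  pd <- subject_profile("p1", "PD", tremor_freq = 4, tremor_amp = 0.1,
                        laterality = 1, tremor_context = "rest",
                        dominant_side = "right")
  rest <- default_protocol()[1, ]
  kinetic <- default_protocol()[7, ]
  set.seed(3)
  left <- generate_signal(pd, rest, "left", "rotation", cfg)
  expect_true(all(left == 0))                 # laterality 1: other wrist flat
  set.seed(3)
  off_context <- generate_signal(pd, kinetic, "right", "rotation", cfg)
  expect_true(all(off_context == 0))          # rest tremor off during kinetic
  set.seed(3)
  on_context <- generate_signal(pd, rest, "right", "rotation", cfg)
  expect_gt(max(abs(on_context)), 0)
})

test_that("the vibration burst is confined to the configured onset window", {
  cfg <- generator_config(seed = 1, gravity_drift_scale = 0, noise_sd = 0,
                          vibration = list(duration = 0.5, amplitude = 0.05,
                                           frequency = 25))
  hc <- subject_profile("h1", "HC")
  step <- default_protocol()[3, ]
  set.seed(5)
  x <- generate_signal(hc, step, "left", "acceleration", cfg)
  burst <- x[1:50, ] - matrix(x[1000, ], 50, 3, byrow = TRUE)
  tail_part <- x[51:1000, ] - matrix(x[1000, ], 950, 3, byrow = TRUE)
  expect_gt(max(abs(burst)), 0.04)
  expect_equal(max(abs(tail_part)), 0)
})

test_that("questionnaire answers are Bernoulli draws of the profile", {
  p0 <- subject_profile("a", "HC", symptom_probs = rep(0, 30))
  p1 <- subject_profile("b", "HC", symptom_probs = rep(1, 30))
  expect_equal(generate_questionnaire(p0), rep(0L, 30))
  expect_equal(generate_questionnaire(p1), rep(1L, 30))
  expect_error(subject_profile("c", "HC", symptom_probs = rep(2, 30)),
               "\\[0, 1\\]")
  expect_error(subject_profile("c", "HC", symptom_probs = rep(0.5, 29)),
               "exactly 30")
  # binomial concentration: per-question mean over 2000 draws at p = 0.5
  ph <- subject_profile("d", "HC", symptom_probs = rep(0.5, 30))
  set.seed(9)
  draws <- t(replicate(2000, generate_questionnaire(ph)))
  expect_true(all(colMeans(draws) >= 0.46 & colMeans(draws) <= 0.54))
})

test_that("generate_profiles honours counts, ranges and determinism", {
  cfg <- generator_config(n_pd = 30, n_hc = 10, n_dd = 5, seed = 3)
  pr <- generate_profiles(cfg)
  expect_length(pr, 45)
  conds <- vapply(pr, `[[`, "", "condition")
  expect_equal(as.vector(table(factor(conds, c("PD", "HC", "DD")))),
               c(30, 10, 5))
  pd <- pr[conds == "PD"]
  freqs <- vapply(pd, `[[`, numeric(1), "tremor_freq")
  expect_true(all(freqs >= 4 & freqs <= 6))
  expect_identical(generate_profiles(cfg), pr)
})
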