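# Shared fixtures for the test suite. Expensive objects are cached for the
# duration of one test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# A compact 3-step protocol covering all three task categories; used where
# the full 11-step protocol would only add runtime, not coverage.
tiny_protocol <- function() {
  data.frame(
    step = c("rest_short", "posture_short", "move_short"),
    duration = c(10, 10, 10),
    category = c("Resting", "Postural", "Kinetic"),
    stringsAsFactors = FALSE
  )
}

# Generate and preprocess a PD-vs-HC cohort on a given protocol.
make_cohort_data <- function(n_pd, n_hc, seed,
                             class_params = default_class_params(),
                             protocol = tiny_protocol(),
                             profiles = NULL, noise_sd = 0.01) {
  cfg <- generator_config(n_pd = n_pd, n_hc = n_hc, protocol = protocol,
                          seed = seed, class_params = class_params,
                          noise_sd = noise_sd)
  cohort <- generate_cohort(cfg, profiles = profiles)
  build_cohort_data(cohort, preprocess_config(removed_steps = character(0)),
                    protocol)
}

# Class parameters with the PD tremor amplitude far above the noise floor.
separated_params <- function() {
  cp <- default_class_params()
  cp$PD$amp <- c(0.05, 0.10)
  cp
}

# PD and HC generated from identical parameters: the downstream pipeline
# should score at chance.
null_params <- function() {
  cp <- default_class_params()
  cp$PD <- cp$HC
  cp
}

# A synthetic cohort_data with features written directly (no signal
# generation), for fast tests of the modeling / stacking / importance layers.
# `delta` shifts the PD class mean in feature space; `quest_delta` shifts the
# PD questionnaire probabilities away from 0.5.
make_fake_data <- function(n_per_class = 12, p = 6, delta = 3, seed = 1,
                           quest_delta = 0) {
  set.seed(seed)
  n <- 2L * n_per_class
  ids <- sprintf("S%03d", seq_len(n))
  labels <- rep(c("PD", "HC"), each = n_per_class)
  genders <- rep(c("male", "female"), length.out = n)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(ids, paste0("f", 1:p)))
  x[labels == "PD", ] <- x[labels == "PD", ] + delta
  attr(x, "col_info") <- data.frame(
    channel = paste0("f", 1:p), feature = paste0("f", 1:p),
    category = rep(c("Resting", "Postural", "Kinetic"), length.out = p),
    sensor = "acceleration", stringsAsFactors = FALSE)
  pm <- matrix(0.5 - quest_delta, n, 30)
  pm[labels == "PD", ] <- 0.5 + quest_delta
  q <- matrix(rbinom(n * 30L, 1L, pm), n, 30,
              dimnames = list(ids, paste0("q", 1:30)))
  structure(list(
    subjects = data.frame(subject_id = ids, label = labels, gender = genders,
                          age = 65, stringsAsFactors = FALSE),
    tensors = NULL, questionnaire = q, manual = x
  ), class = "cohort_data")
}

# One full-protocol PD session (44 recordings), cached.
full_session <- function() {
  cached("full_session", function()
    generate_cohort(generator_config(n_pd = 1, seed = 11))[[1]])
}

# Its preprocessed segments without step removal (14 segments), cached.
full_segments <- function() {
  cached("full_segments", function()
    preprocess_session(full_session(),
                       preprocess_config(removed_steps = character(0))))
}
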