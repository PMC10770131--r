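#' Subject profile for the synthetic cohort generator
#'
#' A subject profile collects the latent phenotype from which a subject's
#' sensor recordings and questionnaire answers are generated: tremor frequency
#' and amplitude, the movement contexts in which the tremor is active (rest,
#' postural, kinetic), side dominance, and the per-item probabilities of
#' answering "yes" to the 30 binary non-motor-symptom questions.
#'
#' @param subject_id Opaque subject identifier.
#' @param condition One of `"PD"`, `"DD"`, `"HC"`.
#' @param gender One of `"male"`, `"female"`.
#' @param age Age in years.
#' @param tremor_freq Tremor frequency in Hz (0 if none).
#' @param tremor_amp Tremor amplitude in g (acceleration units); `>= 0`.
#' @param laterality Fraction in `[0, 1]` of tremor amplitude expressed on the
#'   dominant side; the other side receives `1 - laterality`.
#' @param tremor_context Character subset of `c("rest", "postural", "kinetic")`
#'   naming the task contexts in which the tremor is active.
#' @param symptom_probs Numeric vector of exactly 30 probabilities in `[0, 1]`.
#' @param dominant_side `"left"` or `"right"`.
#'
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, condition, gender = "male", age = 65,
                            tremor_freq = 0, tremor_amp = 0, laterality = 0.5,
                            tremor_context = character(),
                            symptom_probs = rep(0.1, 30),
                            dominant_side = "right") {
  condition <- match.arg(condition, .conditions)
  gender <- match.arg(gender, .genders)
  dominant_side <- match.arg(dominant_side, .wrists)
  assert_number(tremor_amp, "tremor_amp", lower = 0)
  assert_number(tremor_freq, "tremor_freq", lower = 0)
  assert_number(laterality, "laterality", lower = 0, upper = 1)
  if (length(symptom_probs) != 30L)
    stop("symptom_probs must contain exactly 30 probabilities", call. = FALSE)
  if (any(!is.finite(symptom_probs)) || any(symptom_probs < 0) ||
      any(symptom_probs > 1))
    stop("symptom_probs must lie in [0, 1]", call. = FALSE)
  bad <- setdiff(tremor_context, c("rest", "postural", "kinetic"))
  if (length(bad))
    stop("unknown tremor context: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(
    subject_id = as.character(subject_id), condition = condition,
    gender = gender, age = age, tremor_freq = tremor_freq,
    tremor_amp = tremor_amp, laterality = laterality,
    tremor_context = tremor_context, symptom_probs = symptom_probs,
    dominant_side = dominant_side
  ), class = "subject_profile")
}

#' Default per-class generator parameter ranges
#'
#' Encodes the clinical phenotypes the generator emulates: Parkinson's disease
#' with a 4-6 Hz rest tremor that is side-dominant; differential diagnoses
#' (essential tremor and similar) with a 5-8 Hz action/postural tremor; healthy
#' controls with no tremor. Gender marginals and age distributions follow the
#' study cohort (PD male-skewed, controls female-skewed). Questionnaire
#' probabilities are elevated for patients, most strongly in the sleep/fatigue
#' domain for PD.
#'
#' @return Named list with one entry per condition, each holding ranges
#'   (`freq`, `amp`, `laterality` as min/max pairs), `context`,
#'   `symptom_probs` (length 30), `p_male` and `age` (mean, sd).
#' @export
default_class_params <- function() {
  pd_probs <- rep(0.45, 30)
  pd_probs[default_symptom_domains() == "sleep/fatigue"] <- 0.7
  list(
    PD = list(freq = c(4, 6), amp = c(0.02, 0.10), laterality = c(0.7, 0.95),
              context = "rest", symptom_probs = pd_probs,
              p_male = 195 / 276, age = c(65.4, 9.6)),
    DD = list(freq = c(5, 8), amp = c(0.02, 0.10), laterality = c(0.5, 0.8),
              context = c("postural", "kinetic"),
              symptom_probs = rep(0.30, 30),
              p_male = 57 / 114, age = c(62.4, 11.5)),
    HC = list(freq = c(0, 0), amp = c(0, 0), laterality = c(0.5, 0.5),
              context = character(), symptom_probs = rep(0.12, 30),
              p_male = 29 / 79, age = c(62.9, 12.5))
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_pd,n_hc,n_dd Number of subjects per condition (non-negative).
#' @param fs Sampling rate in Hz (default 100).
#' @param protocol Assessment protocol data frame (see [default_protocol()]).
#' @param seed Integer seed making cohort generation fully reproducible.
#' @param class_params Per-class parameter ranges (see
#'   [default_class_params()]).
#' @param gravity_drift_scale Scale of the slow gravitational-orientation
#'   random walk, in g per second.
#' @param noise_sd Standard deviation of the white sensor noise, in g
#'   (acceleration) / rad/s (rotation).
#' @param vibration List with `duration` (s), `amplitude` (g) and `frequency`
#'   (Hz) of the start-of-recording notification vibration burst.
#' @param tremor_jitter Log-normal sigma of the slow multiplicative tremor
#'   amplitude envelope.
#' @param rotation_gain Tremor angular-velocity amplitude (rad/s) produced per
#'   g of acceleration tremor amplitude.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_pd = 0, n_hc = 0, n_dd = 0, fs = 100,
                             protocol = default_protocol(), seed = 1L,
                             class_params = default_class_params(),
                             gravity_drift_scale = 0.01, noise_sd = 0.01,
                             vibration = list(duration = 0.5, amplitude = 0.05,
                                              frequency = 25),
                             tremor_jitter = 0.3, rotation_gain = 2) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive sampling rate in Hz", call. = FALSE)
  validate_protocol(protocol)
  for (nm in c("n_pd", "n_hc", "n_dd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
      stop(nm, " must be a non-negative integer count", call. = FALSE)
  }
  assert_number(gravity_drift_scale, "gravity_drift_scale", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(tremor_jitter, "tremor_jitter", lower = 0)
  assert_number(rotation_gain, "rotation_gain", lower = 0)
  stopifnot(all(c("duration", "amplitude", "frequency") %in% names(vibration)))
  structure(list(
    n_pd = as.integer(n_pd), n_hc = as.integer(n_hc), n_dd = as.integer(n_dd),
    fs = fs, protocol = protocol, seed = seed, class_params = class_params,
    gravity_drift_scale = gravity_drift_scale, noise_sd = noise_sd,
    vibration = vibration, tremor_jitter = tremor_jitter,
    rotation_gain = rotation_gain
  ), class = "generator_config")
}

runif_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else runif(n, range[1], range[2])
}

#' Draw subject profiles for a synthetic cohort
#'
#' Samples one latent phenotype per subject from the class-conditional
#' parameter ranges in `config$class_params`. Uses the current RNG state when
#' `seed = NULL`, otherwise seeds deterministically.
#'
#' @param config A [generator_config()].
#' @param seed Optional seed; defaults to `config$seed`.
#' @return List of [subject_profile()] objects, PD first, then HC, then DD.
#' @export
generate_profiles <- function(config, seed = config$seed) {
  with_seed(seed, {
    counts <- c(PD = config$n_pd, HC = config$n_hc, DD = config$n_dd)
    out <- vector("list", sum(counts))
    k <- 0L
    for (cond in names(counts)) {
      cp <- config$class_params[[cond]]
      n <- counts[[cond]]
      if (n == 0L) next
      for (i in seq_len(n)) {
        k <- k + 1L
        out[[k]] <- subject_profile(
          subject_id = sprintf("%s_%03d", cond, i),
          condition = cond,
          gender = if (runif(1) < cp$p_male) "male" else "female",
          age = min(90, max(30, rnorm(1, cp$age[1], cp$age[2]))),
          tremor_freq = runif_range(1, cp$freq),
          tremor_amp = runif_range(1, cp$amp),
          laterality = runif_range(1, cp$laterality),
          tremor_context = cp$context,
          symptom_probs = cp$symptom_probs,
          dominant_side = if (runif(1) < 0.6) "right" else "left"
        )
      }
    }
    out[seq_len(k)]
  })
}

piecewise_linear_noise <- function(n, fs, knot_spacing, sd) {
  if (sd == 0) return(numeric(n))
  n_knots <- max(2L, ceiling(n / fs / knot_spacing) + 1L)
  knots <- cumsum(c(0, rnorm(n_knots - 1L, 0, sd)))
  approx(seq(0, by = knot_spacing, length.out = n_knots), knots,
         xout = (seq_len(n) - 1L) / fs, rule = 2)$y
}

category_to_context <- c(Resting = "rest", Postural = "postural",
                         Kinetic = "kinetic")

#' Generate one 3-axis sensor recording
#'
#' Simulates a single recording as the sum of (i) a gravitational baseline
#' plus slow piecewise-linear orientation drift (acceleration only), (ii) a
#' tremor sinusoid with a slow log-normal amplitude envelope, gated by the
#' step's task category and scaled by side dominance, (iii) white sensor
#' noise, and (iv) a high-frequency vibration burst confined to the first
#' `config$vibration$duration` seconds of the recording.
#'
#' Uses the current RNG state; wrap in `set.seed()` for reproducibility.
#'
#' @param profile A [subject_profile()].
#' @param step One row of the protocol data frame (fields `step`, `duration`,
#'   `category`).
#' @param wrist `"left"` or `"right"`.
#' @param sensor `"acceleration"` or `"rotation"`.
#' @param config A [generator_config()].
#' @return A numeric matrix with `duration * fs` rows and columns x, y, z.
#' @export
generate_signal <- function(profile, step, wrist, sensor, config) {
  wrist <- match.arg(wrist, .wrists)
  sensor <- match.arg(sensor, .sensors)
  fs <- config$fs
  n <- round(step$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  samples <- matrix(0, nrow = n, ncol = 3L,
                    dimnames = list(NULL, .axes))

  # gravity: unit-magnitude baseline orientation + slow drift (accel only)
  if (sensor == "acceleration") {
    dir <- c(rnorm(2, 0, 0.2), 1)
    base <- dir / sqrt(sum(dir^2))
    for (a in 1:3) {
      samples[, a] <- base[a] +
        piecewise_linear_noise(n, fs, 2.5, config$gravity_drift_scale * 2.5)
    }
  }

  # tremor, gated by task context and laterality
  active <- category_to_context[[step$category]] %in% profile$tremor_context
  amp <- profile$tremor_amp *
    if (wrist == profile$dominant_side) profile$laterality else
      (1 - profile$laterality)
  if (active && amp > 0 && profile$tremor_freq > 0) {
    if (sensor == "rotation") amp <- amp * config$rotation_gain
    w <- abs(rnorm(3, 1, 0.3)); w <- w / sqrt(sum(w^2))
    env <- exp(config$tremor_jitter *
                 piecewise_linear_noise(n, fs, 1, 1)) # slow (<= 1 Hz) envelope
    for (a in 1:3) {
      phase <- runif(1, 0, 2 * pi)
      samples[, a] <- samples[, a] +
        amp * w[a] * env * sin(2 * pi * profile$tremor_freq * t + phase)
    }
  }

  if (config$noise_sd > 0)
    samples <- samples + matrix(rnorm(3L * n, 0, config$noise_sd), ncol = 3L)

  vib <- config$vibration
  if (vib$amplitude > 0 && vib$duration > 0) {
    idx <- t < vib$duration
    burst <- vib$amplitude * sin(2 * pi * vib$frequency * t[idx])
    for (a in 1:3) samples[idx, a] <- samples[idx, a] + burst
  }
  samples
}

#' Generate the 30 binary questionnaire answers
#'
#' Independent Bernoulli draws, one per item, with the profile's per-item
#' probabilities. Uses the current RNG state.
#'
#' @param profile A [subject_profile()].
#' @return Integer vector of 30 values in `{0, 1}`.
#' @export
generate_questionnaire <- function(profile) {
  p <- profile$symptom_probs
  if (any(p < 0 | p > 1)) stop("symptom probabilities must lie in [0, 1]",
                               call. = FALSE)
  as.integer(rbinom(30L, 1L, p))
}

#' Generate a full assessment session for one subject
#'
#' Produces one recording per (protocol step x wrist x sensor), plus the
#' questionnaire, under the subject's latent phenotype. Uses the current RNG
#' state.
#'
#' @inheritParams generate_signal
#' @return An object of class `assessment_session`.
#' @export
generate_session <- function(profile, config) {
  recs <- list()
  for (i in seq_len(nrow(config$protocol))) {
    step <- config$protocol[i, ]
    for (wrist in .wrists) for (sensor in .sensors) {
      samples <- generate_signal(profile, step, wrist, sensor, config)
      key <- paste(step$step, wrist, sensor, sep = "_")
      recs[[key]] <- new_recording(step$step, wrist, sensor, samples,
                                   config$fs)
    }
  }
  new_session(profile$subject_id, profile$condition, profile$gender,
              profile$age, generate_questionnaire(profile), recs)
}

#' Generate a synthetic assessment cohort
#'
#' The entry point of the synthetic-data module: draws subject profiles (or
#' uses supplied ones) and generates one complete assessment session each.
#' Identical `(config, seed)` produce bit-identical cohorts.
#'
#' @param config A [generator_config()].
#' @param profiles Optional list of [subject_profile()] objects overriding the
#'   class-conditional sampling (used to construct cohorts with prescribed
#'   phenotypes).
#' @param seed Seed; defaults to `config$seed`.
#' @return List of `assessment_session` objects.
#' @export
#' @examples
#' cfg <- generator_config(n_pd = 1, n_hc = 1, seed = 7)
#' cohort <- generate_cohort(cfg)
#' length(cohort)
generate_cohort <- function(config, profiles = NULL, seed = config$seed) {
  if (nrow(config$protocol) == 0L)
    stop("protocol must contain at least one step", call. = FALSE)
  with_seed(seed, {
    if (is.null(profiles))
      profiles <- generate_profiles(config, seed = NULL)
    lapply(profiles, generate_session, config = config)
  })
}
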