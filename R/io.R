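# Session containers and JSON persistence.
#
# Layout on disk (one directory per session):
#   metadata.json                      subject metadata + questionnaire
#   <step>_<wrist>_<sensor>.json       one document per recording
# All numbers are serialised as decimal text for lossless round trips; extra
# metadata keys are preserved on read but otherwise ignored.

new_recording <- function(step, wrist, sensor, samples, fs) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    stop("recording must have exactly three axes", call. = FALSE)
  colnames(samples) <- .axes
  structure(list(step = step, wrist = wrist, sensor = sensor,
                 samples = samples, fs = fs),
            class = "assessment_recording")
}

new_session <- function(subject_id, condition, gender, age, questionnaire,
                        recordings, extra = list()) {
  structure(list(subject_id = subject_id, condition = condition,
                 gender = gender, age = age,
                 questionnaire = as.integer(questionnaire),
                 recordings = recordings, extra = extra),
            class = "assessment_session")
}

#' @export
print.assessment_session <- function(x, ...) {
  cat(sprintf("<assessment_session> %s  condition=%s gender=%s age=%.0f\n",
              x$subject_id, x$condition, x$gender, x$age))
  cat(sprintf("  %d recordings, %d questionnaire answers\n",
              length(x$recordings), length(x$questionnaire)))
  invisible(x)
}

#' @export
print.assessment_recording <- function(x, ...) {
  cat(sprintf("<assessment_recording> %s %s %s: %d samples/axis @ %g Hz\n",
              x$step, x$wrist, x$sensor, nrow(x$samples), x$fs))
  invisible(x)
}

#' Write an assessment session to a directory of JSON files
#'
#' Emits one `metadata.json` plus one time-series document per recording,
#' named `<step>_<wrist>_<sensor>.json`. Samples are stored as plain decimal
#' arrays so the files remain readable and editable in any editor, and
#' serialisation is lossless (17 significant digits).
#'
#' @param session An `assessment_session`.
#' @param directory Target directory (created if absent).
#' @return Invisibly, the character vector of files written.
#' @export
write_session <- function(session, directory) {
  stopifnot(inherits(session, "assessment_session"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop("cannot create directory: ", directory, call. = FALSE)
  meta <- c(list(subject_id = session$subject_id,
                 condition = session$condition,
                 gender = session$gender,
                 age = session$age,
                 questionnaire = session$questionnaire),
            session$extra)
  files <- file.path(directory, "metadata.json")
  jsonlite::write_json(meta, files[1], auto_unbox = TRUE, digits = NA)
  for (rec in session$recordings) {
    fn <- file.path(directory,
                    paste0(rec$step, "_", rec$wrist, "_", rec$sensor, ".json"))
    doc <- list(step = rec$step, wrist = rec$wrist, sensor = rec$sensor,
                fs = rec$fs,
                samples = list(x = rec$samples[, 1], y = rec$samples[, 2],
                               z = rec$samples[, 3]))
    jsonlite::write_json(doc, fn, auto_unbox = TRUE, digits = NA)
    files <- c(files, fn)
  }
  invisible(files)
}

#' Read an assessment session from a directory of JSON files
#'
#' Counterpart of [write_session()]; validates the layout and the session
#' invariants (axis lengths equal, condition label in {PD, DD, HC}) and names
#' the offending file in every validation error. Unknown metadata keys are
#' kept in the session's `extra` field.
#'
#' @param directory Directory written by [write_session()] or conforming to
#'   the documented layout.
#' @return An `assessment_session`.
#' @export
read_session <- function(directory) {
  meta_file <- file.path(directory, "metadata.json")
  if (!file.exists(meta_file))
    stop("missing metadata file: ", meta_file, call. = FALSE)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (key in c("subject_id", "condition", "gender", "age", "questionnaire"))
    if (is.null(meta[[key]]))
      stop(meta_file, ": missing required key '", key, "'", call. = FALSE)
  if (!meta$condition %in% .conditions)
    stop(meta_file, ": condition '", meta$condition,
         "' not one of: ", paste(.conditions, collapse = ", "), call. = FALSE)
  extra <- meta[setdiff(names(meta), c("subject_id", "condition", "gender",
                                       "age", "questionnaire"))]
  rec_files <- setdiff(list.files(directory, pattern = "\\.json$"),
                       "metadata.json")
  recs <- list()
  for (fn in sort(rec_files)) {
    path <- file.path(directory, fn)
    doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e)
                      stop(path, ": unparseable JSON (", conditionMessage(e),
                           ")", call. = FALSE))
    for (key in c("step", "wrist", "sensor", "fs", "samples"))
      if (is.null(doc[[key]]))
        stop(path, ": missing required key '", key, "'", call. = FALSE)
    ax <- doc$samples
    lens <- lengths(ax[c("x", "y", "z")])
    if (length(unique(lens)) != 1L)
      stop(path, ": axes have unequal lengths (",
           paste(lens, collapse = ", "), ")", call. = FALSE)
    samples <- cbind(x = as.numeric(ax$x), y = as.numeric(ax$y),
                     z = as.numeric(ax$z))
    if (any(!is.finite(samples)))
      stop(path, ": non-finite or non-numeric sample values", call. = FALSE)
    key <- paste(doc$step, doc$wrist, doc$sensor, sep = "_")
    if (!is.null(recs[[key]]))
      stop(path, ": duplicate recording for (", key, ")", call. = FALSE)
    recs[[key]] <- new_recording(doc$step, doc$wrist, doc$sensor, samples,
                                 doc$fs)
  }
  new_session(meta$subject_id, meta$condition, meta$gender, meta$age,
              meta$questionnaire, recs, extra = extra)
}

#' Assemble preprocessed segments into the fixed-order channel tensor
#'
#' Stacks the 10-second single-axis series of one subject into a matrix with
#' one column per channel, ordered task-segment-major, then arm (left, right),
#' sensor (acceleration, rotation) and axis (x, y, z). For the full protocol
#' and both sensors this yields 14 segments x 2 x 2 x 3 = 168 channels.
#'
#' @param segments Named list of preprocessed segment recordings (as produced
#'   by [preprocess_session()]), keyed `<segment>_<wrist>_<sensor>`, each an
#'   `assessment_recording` whose `step` is the segment name and which carries
#'   a `category` attribute.
#' @param subject_id Subject identifier attached to the tensor.
#' @param selected_sensors Subset of `c("acceleration", "rotation")`.
#' @return An object of class `channel_tensor`: list with `subject_id`,
#'   `channels` (samples x channels matrix) and `info` (data frame with one
#'   row per channel: `segment`, `arm`, `sensor`, `axis`, `category`, `label`).
#' @export
assemble_channels <- function(segments, subject_id = NULL,
                              selected_sensors = .sensors) {
  selected_sensors <- match.arg(selected_sensors, .sensors,
                                several.ok = TRUE)
  seg_keys <- vapply(segments, function(r)
    paste(r$step, r$wrist, r$sensor, sep = "_"), character(1))
  names(segments) <- seg_keys
  seg_names <- unique(vapply(segments, function(r) r$step, character(1)))
  n_samples <- unique(vapply(segments, function(r) nrow(r$samples),
                             integer(1)))
  if (length(n_samples) != 1L)
    stop("segments have unequal lengths; preprocess first", call. = FALSE)
  cols <- list(); info <- list()
  for (seg in seg_names) for (arm in .wrists) for (sensor in selected_sensors) {
    key <- paste(seg, arm, sensor, sep = "_")
    rec <- segments[[key]]
    if (is.null(rec))
      stop("missing recording for (", seg, ", ", arm, ", ", sensor, ")",
           call. = FALSE)
    category <- attr(rec, "category") %||% "Resting"
    for (a in 1:3) {
      label <- paste(seg, arm, sensor, .axes[a], sep = "_")
      cols[[label]] <- rec$samples[, a]
      info[[label]] <- data.frame(segment = seg, arm = arm, sensor = sensor,
                                  axis = .axes[a], category = category,
                                  label = label, stringsAsFactors = FALSE)
    }
  }
  channels <- do.call(cbind, cols)
  structure(list(subject_id = subject_id, channels = channels,
                 info = do.call(rbind, c(info, make.row.names = FALSE))),
            class = "channel_tensor")
}

#' @export
print.channel_tensor <- function(x, ...) {
  cat(sprintf("<channel_tensor> %s: %d channels x %d samples\n",
              x$subject_id %||% "?", ncol(x$channels), nrow(x$channels)))
  cat("  categories: ",
      paste(sprintf("%s=%d", names(table(x$info$category)),
                    table(x$info$category)), collapse = ", "), "\n")
  invisible(x)
}
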