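#' Assemble a cohort into analysis-ready containers
#'
#' Runs preprocessing and channel assembly for every session and precomputes
#' the fold-independent manual (option A) feature matrix. BOSS (option B)
#' features are *not* precomputed: their quantisation bins must be fitted
#' within each training fold (see [boss_cohort_fit()]).
#'
#' @param cohort List of `assessment_session`s.
#' @param pre_config A [preprocess_config()].
#' @param protocol The assessment protocol.
#' @param manual_config A [manual_feature_config()].
#' @return An object of class `cohort_data`: `subjects` (data frame with
#'   `subject_id`, `label`, `gender`, `age`), `tensors` (named list of
#'   `channel_tensor`s), `questionnaire` (subjects x 30 binary matrix) and
#'   `manual` (subjects x features matrix with a `"col_info"` attribute).
#' @export
build_cohort_data <- function(cohort, pre_config = preprocess_config(),
                              protocol = default_protocol(),
                              manual_config = manual_feature_config()) {
  stopifnot(length(cohort) > 0)
  ids <- vapply(cohort, `[[`, "", "subject_id")
  subjects <- data.frame(
    subject_id = ids,
    label = vapply(cohort, `[[`, "", "condition"),
    gender = vapply(cohort, `[[`, "", "gender"),
    age = vapply(cohort, function(s) as.numeric(s$age), numeric(1)),
    stringsAsFactors = FALSE
  )
  tensors <- lapply(cohort, function(s)
    assemble_channels(preprocess_session(s, pre_config, protocol),
                      subject_id = s$subject_id))
  names(tensors) <- ids
  quest <- do.call(rbind, lapply(cohort, `[[`, "questionnaire"))
  colnames(quest) <- paste0("q", seq_len(ncol(quest)))
  rownames(quest) <- ids

  rows <- lapply(tensors, featurize_manual, config = manual_config)
  manual <- do.call(rbind, rows)
  rownames(manual) <- ids
  attr(manual, "col_info") <- attr(rows[[1]], "col_info")

  structure(list(subjects = subjects, tensors = tensors,
                 questionnaire = quest, manual = manual),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> %d subjects (%s)\n", nrow(x$subjects),
              paste(sprintf("%s=%d", names(table(x$subjects$label)),
                            table(x$subjects$label)), collapse = ", ")))
  cat(sprintf("  %d channels/subject, %d manual features, %d questionnaire items\n",
              ncol(x$tensors[[1]]$channels), ncol(x$manual),
              ncol(x$questionnaire)))
  invisible(x)
}

subset_tensor <- function(tensor, sensors) {
  keep <- tensor$info$sensor %in% sensors
  structure(list(subject_id = tensor$subject_id,
                 channels = tensor$channels[, keep, drop = FALSE],
                 info = tensor$info[keep, , drop = FALSE]),
            class = "channel_tensor")
}

input_sensors <- function(input_source) {
  switch(input_source,
         acceleration = "acceleration",
         rotation = "rotation",
         both = c("acceleration", "rotation"),
         stop("no sensor set for input source: ", input_source,
              call. = FALSE))
}

#' Extract the feature matrix for one grid point
#'
#' All feature fitting (BOSS quantisation bins) happens on `train_ids` only;
#' the fitted transform is then applied to `ids`. Option A and questionnaire
#' features involve no fitting and are plain lookups.
#'
#' @param data A `cohort_data`.
#' @param setup A [grid_point()].
#' @param train_ids Subject ids available for feature fitting.
#' @param ids Subject ids to featurise.
#' @return Numeric matrix (subjects x features) with a `"col_info"`
#'   attribute.
#' @export
extract_features <- function(data, setup, train_ids, ids) {
  if (setup$option == "Q") {
    x <- data$questionnaire[ids, , drop = FALSE]
    attr(x, "col_info") <- data.frame(
      channel = colnames(x), feature = colnames(x),
      category = default_symptom_domains(), sensor = "questionnaire",
      stringsAsFactors = FALSE)
    return(x)
  }
  sensors <- input_sensors(setup$input_source)
  if (setup$option == "A") {
    info <- attr(data$manual, "col_info")
    keep <- info$sensor %in% sensors
    x <- data$manual[ids, keep, drop = FALSE]
    attr(x, "col_info") <- info[keep, , drop = FALSE]
    x
  } else {
    p <- setup$params
    fit <- boss_cohort_fit(
      lapply(data$tensors[train_ids], subset_tensor, sensors = sensors),
      windows = p$windows %||% c(20, 40, 80),
      word_length = p$word_length %||% 4,
      alphabet_size = p$alphabet_size %||% 4,
      normalize_windows = p$normalize_windows %||% TRUE,
      numerosity_reduction = p$numerosity_reduction %||% TRUE,
      binning = p$binning %||% "equi-depth")
    rows <- lapply(data$tensors[ids], function(tn)
      featurize_boss(fit, subset_tensor(tn, sensors)))
    x <- do.call(rbind, rows)
    rownames(x) <- ids
    attr(x, "col_info") <- attr(rows[[1]], "col_info")
    x
  }
}
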