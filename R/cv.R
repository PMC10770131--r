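#' Subject-level stratified cross-validation plan
#'
#' Partitions subjects (never individual segments) into `outer_k` folds,
#' stratified by class label, under a fixed seed. Binding all assessment
#' steps of one individual to one fold prevents identity confounding: no
#' sub-series of a subject can appear in both train and test.
#'
#' @param subject_ids Character vector of subject identifiers.
#' @param labels Class label per subject.
#' @param outer_k Number of outer folds (default 5).
#' @param inner_k Number of inner folds used for hyperparameter selection
#'   (default 5).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return An object of class `cv_plan`: data frame `assignment`
#'   (`subject_id`, `label`, `fold`) plus `outer_k`, `inner_k`, `seed`.
#' @export
make_cv_plan <- function(subject_ids, labels, outer_k = 5, inner_k = 5,
                         seed = 1L) {
  if (length(subject_ids) != length(labels))
    stop("subject_ids and labels must have equal length", call. = FALSE)
  if (anyDuplicated(subject_ids))
    stop("subject_ids must be unique", call. = FALSE)
  tab <- table(labels)
  small <- names(tab)[tab < outer_k]
  if (length(small))
    stop("class(es) with fewer subjects than folds: ",
         paste(small, collapse = ", "), call. = FALSE)
  fold <- integer(length(subject_ids))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(outer_k), length(idx))
    }
  })
  structure(list(
    assignment = data.frame(subject_id = as.character(subject_ids),
                            label = as.character(labels), fold = fold,
                            stringsAsFactors = FALSE),
    outer_k = outer_k, inner_k = inner_k, seed = seed
  ), class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d subjects, %d outer / %d inner folds, seed %s\n",
              nrow(x$assignment), x$outer_k, x$inner_k, x$seed))
  print(table(x$assignment$label, x$assignment$fold))
  invisible(x)
}

#' Gender-by-class balanced sample weights
#'
#' Weights inversely proportional to group frequencies, where a group is a
#' non-empty (gender, class) cell: `w_g = N / (G * n_g)` with `N` subjects,
#' `G` non-empty groups and `n_g` the group size. Every group then carries
#' equal total weight mass `N / G`, preventing the classifiers from exploiting
#' gender or class imbalance.
#'
#' @param labels Class label per subject.
#' @param genders Gender per subject.
#' @return Numeric weight per subject.
#' @export
compute_sample_weights <- function(labels, genders) {
  if (!length(labels)) stop("empty input", call. = FALSE)
  if (length(labels) != length(genders))
    stop("labels and genders must have equal length", call. = FALSE)
  group <- paste(genders, labels, sep = ":")
  tab <- table(group)
  N <- length(labels); G <- length(tab)
  unname(N / (G * as.numeric(tab[group])))
}

#' Classification metric suite
#'
#' Balanced accuracy (mean of per-class recalls, robust to class imbalance)
#' plus precision, recall and F1 for the designated positive class.
#'
#' @param y_true True labels; every class must be present.
#' @param y_pred Predicted labels.
#' @param positive The positive class (default `"PD"`).
#' @return Named numeric vector `(balanced_accuracy, f1, precision, recall)`,
#'   all in `[0, 1]`.
#' @export
metrics <- function(y_true, y_pred, positive = "PD") {
  if (length(y_true) != length(y_pred))
    stop("label vectors must have equal length", call. = FALSE)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(y_true))
  if (length(classes) < 2L)
    stop("balanced accuracy undefined: class absent from y_true",
         call. = FALSE)
  recalls <- vapply(classes, function(cl)
    mean(y_pred[y_true == cl] == cl), numeric(1))
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(balanced_accuracy = mean(recalls), f1 = f1, precision = precision,
    recall = recall)
}

#' Gender-matched test subset by random under-sampling
#'
#' Within each gender, both classes are under-sampled to the smaller
#' (gender, class) cell, so the gender proportion becomes identical across
#' the two classes. Deterministic under the seed.
#'
#' @param subjects Data frame with columns `subject_id`, `label`, `gender`
#'   (two classes present).
#' @param seed Integer seed.
#' @return Character vector of retained subject ids.
#' @export
gender_match_subset <- function(subjects, seed = 1L) {
  classes <- unique(subjects$label)
  if (length(classes) != 2L)
    stop("gender matching requires exactly two classes", call. = FALSE)
  keep <- character(0)
  with_seed(seed, {
    for (g in unique(subjects$gender)) {
      cells <- lapply(classes, function(cl)
        subjects$subject_id[subjects$gender == g & subjects$label == cl])
      sizes <- lengths(cells)
      if (any(sizes == 0L)) {
        empty <- classes[sizes == 0L][1]
        stop("empty gender-by-class cell: (", g, ", ", empty, ")",
             call. = FALSE)
      }
      m <- min(sizes)
      for (cell in cells)
        keep <- c(keep, if (length(cell) == m) cell else sample(cell, m))
    }
  })
  keep
}
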