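# Multimodal classifier stacking: one sub-classifier per data modality
# (smartwatch features, questionnaire answers), combined by a logistic
# meta-classifier trained on cross-validated out-of-fold probabilities.

#' Fit a two-modality stacked classifier
#'
#' Meta-features are out-of-fold positive-class probabilities: the training
#' subjects are split into `inner_k` stratified folds and each subject's
#' meta-feature comes from sub-models that never saw it. The logistic
#' meta-classifier (unpenalised, intercept on) is fitted on these
#' probabilities; the sub-models are then refit on the full training fold for
#' prediction. Sample weights apply to every fit.
#'
#' @param sensor_x Sensor feature matrix (training subjects x features).
#' @param quest_x Questionnaire matrix (training subjects x 30).
#' @param y Factor of class labels (second level = positive class).
#' @param weights Per-subject sample weights.
#' @param sensor_spec,quest_spec [grid_point()]s naming classifier and
#'   hyperparameters per modality.
#' @param inner_k Folds for the out-of-fold meta-feature construction.
#' @param seed Integer seed.
#' @return An object of class `stacked_model`, holding the refit sub-models,
#'   the meta-classifier, the meta-feature matrix (one row per training
#'   subject, one column per sub-model) and the fold bookkeeping
#'   (`meta_folds`).
#' @export
fit_stack <- function(sensor_x, quest_x, y, weights = rep(1, length(y)),
                      sensor_spec = grid_point("both", "A", "svm"),
                      quest_spec = grid_point("questionnaire", "Q", "gbt"),
                      inner_k = 5, seed = 1L) {
  y <- droplevels(as.factor(y))
  stopifnot(nrow(sensor_x) == length(y), nrow(quest_x) == length(y))
  n <- length(y)
  ids <- rownames(sensor_x) %||% as.character(seq_len(n))
  plan <- make_cv_plan(ids, as.character(y), outer_k = inner_k,
                       inner_k = inner_k, seed = derive_seed(seed, "stack"))
  folds <- plan$assignment$fold[match(ids, plan$assignment$subject_id)]

  meta_x <- matrix(NA_real_, n, 2,
                   dimnames = list(ids, c("sensor", "questionnaire")))
  for (f in seq_len(inner_k)) {
    tr <- folds != f; te <- !tr
    ms <- fit_classifier(sensor_x[tr, , drop = FALSE], y[tr], weights[tr],
                         sensor_spec$classifier, sensor_spec$params,
                         seed = derive_seed(seed, "oof_sensor", f))
    mq <- fit_classifier(quest_x[tr, , drop = FALSE], y[tr], weights[tr],
                         quest_spec$classifier, quest_spec$params,
                         seed = derive_seed(seed, "oof_quest", f))
    meta_x[te, 1] <- predict(ms, sensor_x[te, , drop = FALSE], type = "prob")
    meta_x[te, 2] <- predict(mq, quest_x[te, , drop = FALSE], type = "prob")
  }
  stopifnot(!anyNA(meta_x))

  meta_df <- data.frame(y01 = as.numeric(y) - 1, sensor = meta_x[, 1],
                        questionnaire = meta_x[, 2])
  meta <- suppressWarnings(
    stats::glm(y01 ~ sensor + questionnaire, family = stats::binomial(),
               data = meta_df, weights = weights))

  sensor_model <- fit_classifier(sensor_x, y, weights,
                                 sensor_spec$classifier, sensor_spec$params,
                                 seed = derive_seed(seed, "final_sensor"))
  quest_model <- fit_classifier(quest_x, y, weights,
                                quest_spec$classifier, quest_spec$params,
                                seed = derive_seed(seed, "final_quest"))
  structure(list(submodels = list(sensor = sensor_model,
                                  questionnaire = quest_model),
                 meta = meta, meta_features = meta_x, meta_folds = folds,
                 levels = levels(y), positive = levels(y)[2L],
                 specs = list(sensor = sensor_spec, quest = quest_spec)),
            class = "stacked_model")
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf("<stacked_model> positive class: %s\n", x$positive))
  cat(sprintf("  sensor sub-model:        %s\n", setup_string(x$specs$sensor)))
  cat(sprintf("  questionnaire sub-model: %s\n", setup_string(x$specs$quest)))
  cat("  meta coefficients:", paste(sprintf("%s=%.3f",
                                            names(stats::coef(x$meta)),
                                            stats::coef(x$meta)),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Predict with a stacked classifier
#'
#' Passes each modality through its refit sub-model and the resulting
#' positive-class probabilities through the logistic meta-classifier.
#'
#' @param object A `stacked_model`.
#' @param newdata Named list with elements `sensor` and `questionnaire`
#'   (matrices with matching columns and identical row order). Both
#'   modalities are required; there is no imputation.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return Factor of labels or numeric vector of probabilities.
#' @export
predict.stacked_model <- function(object, newdata, type = c("class", "prob"),
                                  ...) {
  type <- match.arg(type)
  for (mod in c("sensor", "questionnaire"))
    if (is.null(newdata[[mod]]))
      stop("missing modality '", mod, "' in newdata", call. = FALSE)
  ps <- predict(object$submodels$sensor, newdata$sensor, type = "prob")
  pq <- predict(object$submodels$questionnaire, newdata$questionnaire,
                type = "prob")
  prob <- stats::predict(object$meta,
                         newdata = data.frame(sensor = ps,
                                              questionnaire = pq),
                         type = "response")
  if (type == "prob") unname(prob)
  else factor(ifelse(prob >= 0.5, object$levels[2L], object$levels[1L]),
              levels = object$levels)
}

#' Nested cross-validation with classifier stacking
#'
#' Per outer fold, the best sensor setup is selected on the training fold via
#' the inner grid search, the questionnaire sub-model is the gradient-boosted
#' tree classifier on the 30 raw binary answers, and the two are combined by
#' [fit_stack()]. The report scores each modality alone (its refit sub-model)
#' and the stacked classifier on the same untouched test fold.
#'
#' @inheritParams evaluate_nested
#' @param sensor_grid Grid of sensor setups searched in the inner loop.
#' @param quest_spec Questionnaire sub-model specification.
#' @return An `evaluation_report` whose `folds` carry a `modality` column
#'   (`sensor`, `questionnaire`, `stacked`).
#' @export
evaluate_stack <- function(data, task = c("PD", "HC"),
                           sensor_grid = default_grid(),
                           quest_spec = grid_point("questionnaire", "Q",
                                                   "gbt",
                                                   list(nrounds = 100,
                                                        max_depth = 4)),
                           outer_k = 5, inner_k = 5, seed = 1L,
                           matched = TRUE) {
  positive <- task[1]
  sub <- data$subjects[data$subjects$label %in% task, ]
  plan <- make_cv_plan(sub$subject_id, sub$label, outer_k, inner_k, seed)
  rows <- list()
  for (f in seq_len(outer_k)) {
    tr <- plan$assignment$subject_id[plan$assignment$fold != f]
    te <- plan$assignment$subject_id[plan$assignment$fold == f]
    sel <- grid_search_inner(data, tr, sensor_grid, inner_k,
                             seed = derive_seed(seed, "grid", f), positive)
    g <- sel$best
    str <- sub[match(tr, sub$subject_id), ]
    y_tr <- label_factor(str$label, positive)
    w <- compute_sample_weights(str$label, str$gender)
    sensor_tr <- extract_features(data, g, tr, tr)
    sensor_te <- extract_features(data, g, tr, te)
    quest_tr <- data$questionnaire[tr, , drop = FALSE]
    quest_te <- data$questionnaire[te, , drop = FALSE]
    model <- fit_stack(sensor_tr, quest_tr, y_tr, w, sensor_spec = g,
                       quest_spec = quest_spec, inner_k = inner_k,
                       seed = derive_seed(seed, "stackfit", f))
    y_te <- sub$label[match(te, sub$subject_id)]
    ste <- sub[match(te, sub$subject_id), ]
    msub <- if (matched) tryCatch(
      gender_match_subset(ste, seed = derive_seed(seed, "match", f)),
      error = function(e) NULL) else NULL

    preds <- list(
      sensor = as.character(predict(model$submodels$sensor, sensor_te)),
      questionnaire = as.character(predict(model$submodels$questionnaire,
                                           quest_te)),
      stacked = as.character(predict(model, list(sensor = sensor_te,
                                                 questionnaire = quest_te)))
    )
    for (mod in names(preds)) {
      m <- metrics(y_te, preds[[mod]], positive)
      m_sub <- rep(NA_real_, 4)
      if (!is.null(msub)) {
        keep <- te %in% msub
        m_sub <- tryCatch(metrics(y_te[keep], preds[[mod]][keep], positive),
                          error = function(e) rep(NA_real_, 4))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, modality = mod,
        setup = if (mod == "questionnaire") setup_string(quest_spec) else
          setup_string(g),
        input_source = g$input_source, option = g$option,
        classifier = g$classifier, n_test = length(te),
        balanced_accuracy = m[["balanced_accuracy"]], f1 = m[["f1"]],
        precision = m[["precision"]], recall = m[["recall"]],
        matched_balanced_accuracy = m_sub[[1]], matched_f1 = m_sub[[2]],
        matched_precision = m_sub[[3]], matched_recall = m_sub[[4]],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(folds = do.call(rbind, rows), task = task, seed = seed,
                 plan = plan, grid = sensor_grid, stacked = TRUE),
            class = "evaluation_report")
}
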