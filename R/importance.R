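#' Default mapping of the 30 questionnaire items into symptom domains
#'
#' The 30 binary non-motor-symptom items are grouped into the nine
#' conventional domains of the non-motor-symptom questionnaire
#' (gastrointestinal, urinary, apathy/attention/memory,
#' hallucinations/delusions, depression/anxiety, sexual function,
#' cardiovascular, sleep/fatigue, miscellaneous). The mapping is a package
#' default and can be overridden wherever a grouping is accepted.
#'
#' @return Character vector of 30 domain names, one per item.
#' @export
default_symptom_domains <- function() {
  rep(c("gastrointestinal", "urinary", "apathy/attention/memory",
        "hallucinations/delusions", "depression/anxiety", "sexual function",
        "cardiovascular", "sleep/fatigue", "miscellaneous"),
      times = c(7, 2, 3, 2, 2, 2, 2, 5, 5))
}

check_partition <- function(groups, p) {
  idx <- unlist(groups, use.names = FALSE)
  if (!length(groups) || any(lengths(groups) == 0L))
    stop("groups must be non-empty", call. = FALSE)
  if (length(idx) != p || anyDuplicated(idx) || !setequal(idx, seq_len(p)))
    stop("groups must partition the feature columns exactly", call. = FALSE)
}

#' Grouped permutation feature importance
#'
#' For each feature group and repeat, all of the group's columns are jointly
#' shuffled across test subjects with one shared permutation (preserving the
#' within-group joint structure), the model is rescored, and the drop in
#' balanced accuracy relative to the unpermuted baseline is recorded. The
#' returned importance is the per-group mean drop over repeats.
#'
#' @param model A fitted model.
#' @param x Test feature matrix, untouched by training.
#' @param y True test labels.
#' @param groups Named list of column indices partitioning `1:ncol(x)`.
#' @param n_repeats Permutation repeats per group (default 50).
#' @param seed Integer seed.
#' @param predict_fun Function `(model, x) -> labels`; defaults to
#'   `predict(model, x)`.
#' @param positive Positive class label for the metric suite.
#' @return An object of class `group_importance`: data frame `importance`
#'   (`group`, `mean_drop`, `sd_drop`) plus the baseline balanced accuracy.
#' @export
grouped_permutation_importance <- function(model, x, y, groups,
                                           n_repeats = 50, seed = 1L,
                                           predict_fun = NULL,
                                           positive = "PD") {
  x <- as.matrix(x)
  check_partition(groups, ncol(x))
  if (is.null(predict_fun))
    predict_fun <- function(model, x) predict(model, x)
  score <- function(xx) metrics(y, as.character(predict_fun(model, xx)),
                                positive)[["balanced_accuracy"]]
  baseline <- score(x)
  n <- nrow(x)
  drops <- matrix(NA_real_, n_repeats, length(groups),
                  dimnames = list(NULL, names(groups)))
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      for (gi in seq_along(groups)) {
        perm <- sample.int(n)
        xp <- x
        cols <- groups[[gi]]
        xp[, cols] <- x[perm, cols, drop = FALSE]
        drops[r, gi] <- baseline - score(xp)
      }
    }
  })
  structure(list(
    importance = data.frame(group = names(groups),
                            mean_drop = colMeans(drops),
                            sd_drop = apply(drops, 2, stats::sd),
                            stringsAsFactors = FALSE,
                            row.names = NULL),
    baseline = baseline, n_repeats = n_repeats
  ), class = "group_importance")
}

#' Rank feature groups by importance
#'
#' Sorts groups descending by mean balanced-accuracy drop; exact ties keep
#' their input order (stable sort).
#'
#' @param imp A `group_importance`, or a data frame with columns `group`,
#'   `mean_drop` (and optionally `sd_drop`).
#' @return Data frame sorted by decreasing importance, with a `rank` column.
#' @export
rank_groups <- function(imp) {
  df <- if (inherits(imp, "group_importance")) imp$importance else imp
  ord <- order(-df$mean_drop, seq_len(nrow(df)))
  out <- df[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.group_importance <- function(x, ...) {
  cat(sprintf("<group_importance> baseline balanced accuracy %.2f%%, %d repeats\n",
              100 * x$baseline, x$n_repeats))
  print(rank_groups(x), row.names = FALSE)
  invisible(x)
}

# Build the partition of a combined [sensor | questionnaire] matrix into
# assessment-step-category groups and symptom-domain groups.
combined_feature_groups <- function(sensor_col_info, n_quest = 30,
                                    domains = default_symptom_domains()) {
  groups <- list()
  for (cat in unique(sensor_col_info$category))
    groups[[paste(cat, "tasks")]] <- which(sensor_col_info$category == cat)
  offset <- nrow(sensor_col_info)
  for (d in unique(domains))
    groups[[d]] <- offset + which(domains == d)
  groups
}

#' Grouped importance of the stacked model across test folds
#'
#' Reproduces the importance analysis of the full pipeline: per outer fold a
#' stacked model is fitted on the training fold, the grouped permutation
#' importance (sensor features grouped by assessment-step task category,
#' questionnaire items by symptom domain) is computed on the test fold, and
#' the drops are averaged across random repeats and all test folds.
#'
#' @inheritParams evaluate_stack
#' @param sensor_setup The sensor-modality [grid_point()] used in every fold
#'   (fix it to the winning setup of a prior [evaluate_stack()] run, or leave
#'   the default).
#' @param n_repeats Permutation repeats per group and fold.
#' @param domains Item-to-domain mapping for the questionnaire columns.
#' @return A `group_importance` whose drops are averaged over repeats and
#'   folds, with a `per_fold` element.
#' @export
stack_importance <- function(data, task = c("PD", "HC"),
                             sensor_setup = grid_point("both", "A", "svm"),
                             quest_spec = grid_point("questionnaire", "Q",
                                                     "gbt",
                                                     list(nrounds = 100,
                                                          max_depth = 4)),
                             outer_k = 5, inner_k = 5, seed = 1L,
                             n_repeats = 50,
                             domains = default_symptom_domains()) {
  positive <- task[1]
  sub <- data$subjects[data$subjects$label %in% task, ]
  plan <- make_cv_plan(sub$subject_id, sub$label, outer_k, inner_k, seed)
  per_fold <- list()
  for (f in seq_len(outer_k)) {
    tr <- plan$assignment$subject_id[plan$assignment$fold != f]
    te <- plan$assignment$subject_id[plan$assignment$fold == f]
    str <- sub[match(tr, sub$subject_id), ]
    y_tr <- label_factor(str$label, positive)
    w <- compute_sample_weights(str$label, str$gender)
    sensor_tr <- extract_features(data, sensor_setup, tr, tr)
    sensor_te <- extract_features(data, sensor_setup, tr, te)
    quest_tr <- data$questionnaire[tr, , drop = FALSE]
    quest_te <- data$questionnaire[te, , drop = FALSE]
    model <- fit_stack(sensor_tr, quest_tr, y_tr, w,
                       sensor_spec = sensor_setup, quest_spec = quest_spec,
                       inner_k = inner_k,
                       seed = derive_seed(seed, "stackfit", f))
    ps <- ncol(sensor_te)
    groups <- combined_feature_groups(attr(sensor_te, "col_info"),
                                      n_quest = ncol(quest_te),
                                      domains = domains)
    x_comb <- cbind(sensor_te, quest_te)
    y_te <- sub$label[match(te, sub$subject_id)]
    pred_fun <- function(model, x)
      predict(model, list(sensor = x[, seq_len(ps), drop = FALSE],
                          questionnaire = x[, ps + seq_len(ncol(quest_te)),
                                            drop = FALSE]))
    per_fold[[f]] <- grouped_permutation_importance(
      model, x_comb, y_te, groups, n_repeats = n_repeats,
      seed = derive_seed(seed, "perm", f), predict_fun = pred_fun,
      positive = positive)
  }
  agg <- per_fold[[1]]$importance
  agg$mean_drop <- rowMeans(vapply(per_fold, function(p)
    p$importance$mean_drop, numeric(nrow(agg))))
  agg$sd_drop <- apply(vapply(per_fold, function(p)
    p$importance$mean_drop, numeric(nrow(agg))), 1, stats::sd)
  structure(list(importance = agg,
                 baseline = mean(vapply(per_fold, `[[`, numeric(1),
                                        "baseline")),
                 n_repeats = n_repeats, per_fold = per_fold),
            class = "group_importance")
}
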