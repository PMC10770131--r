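# Nested cross-validation: inner grid search for setup selection, outer folds
# for unbiased scoring, all at subject level.

label_factor <- function(labels, positive) {
  neg <- setdiff(unique(labels), positive)
  if (length(neg) != 1L)
    stop("need exactly two classes; got: ",
         paste(unique(labels), collapse = ", "), call. = FALSE)
  factor(labels, levels = c(neg, positive))
}

#' Inner-loop grid search
#'
#' Scores every grid point by mean balanced accuracy over an inner
#' cross-validation confined to the training fold, with all feature fitting
#' (BOSS bins, scalers) done inside each inner training split, and returns
#' the maximiser. Ties break deterministically to the first point in
#' enumeration order; a grid of one point is returned directly. Points whose
#' training fails are skipped with a warning.
#'
#' @param data A `cohort_data`.
#' @param train_ids Subject ids of the training fold.
#' @param grid List of [grid_point()]s.
#' @param inner_k Number of inner folds.
#' @param seed Integer seed.
#' @param positive Positive class label.
#' @return List with `best` (the selected grid point), `best_index` and
#'   `scores` (mean inner balanced accuracy per grid point).
#' @export
grid_search_inner <- function(data, train_ids, grid, inner_k = 5, seed = 1L,
                              positive = "PD") {
  if (!length(grid)) stop("grid must be non-empty", call. = FALSE)
  if (length(grid) == 1L)
    return(list(best = grid[[1]], best_index = 1L, scores = NA_real_))
  sub <- data$subjects[match(train_ids, data$subjects$subject_id), ]
  plan <- make_cv_plan(train_ids, sub$label, outer_k = inner_k,
                       inner_k = inner_k, seed = derive_seed(seed, "inner"))
  scores <- vapply(seq_along(grid), function(gi) {
    g <- grid[[gi]]
    fold_scores <- tryCatch({
      vapply(seq_len(inner_k), function(f) {
        tr <- plan$assignment$subject_id[plan$assignment$fold != f]
        va <- plan$assignment$subject_id[plan$assignment$fold == f]
        str <- sub[match(tr, sub$subject_id), ]
        y_tr <- label_factor(str$label, positive)
        w <- compute_sample_weights(str$label, str$gender)
        x_tr <- extract_features(data, g, tr, tr)
        x_va <- extract_features(data, g, tr, va)
        model <- fit_classifier(x_tr, y_tr, w, g$classifier, g$params,
                                seed = derive_seed(seed, "fit", gi * 100 + f))
        y_va <- sub$label[match(va, sub$subject_id)]
        metrics(y_va, as.character(predict(model, x_va)),
                positive = positive)[["balanced_accuracy"]]
      }, numeric(1))
    }, error = function(e) {
      warning("grid point ", gi, " failed: ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
    mean(fold_scores)
  }, numeric(1))
  if (all(is.na(scores)))
    stop("all grid points failed during inner cross-validation",
         call. = FALSE)
  best <- which.max(scores)  # first maximum wins (stable tie-break)
  list(best = grid[[best]], best_index = best, scores = scores)
}

setup_string <- function(g) paste(g$input_source, g$option, g$classifier,
                                  sep = "/")

#' Nested cross-validation evaluation
#'
#' For each outer fold: select the best setup on the training fold via
#' [grid_search_inner()], refit it on the whole training fold with
#' gender-by-class sample weights, and score the untouched test fold — both
#' in full and on its gender-matched subset.
#'
#' @param data A `cohort_data`.
#' @param task Character pair `(positive class, negative class)`, e.g.
#'   `c("PD", "HC")` or `c("PD", "DD")`.
#' @param grid List of [grid_point()]s.
#' @param outer_k,inner_k Fold counts (defaults 5).
#' @param seed Integer seed fixing fold assignment and all stochastic fits.
#' @param matched Also score the gender-matched under-sampled test subset.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_nested <- function(data, task = c("PD", "HC"), grid = default_grid(),
                            outer_k = 5, inner_k = 5, seed = 1L,
                            matched = TRUE) {
  positive <- task[1]
  sub <- data$subjects[data$subjects$label %in% task, ]
  plan <- make_cv_plan(sub$subject_id, sub$label, outer_k, inner_k, seed)
  rows <- vector("list", outer_k)
  for (f in seq_len(outer_k)) {
    tr <- plan$assignment$subject_id[plan$assignment$fold != f]
    te <- plan$assignment$subject_id[plan$assignment$fold == f]
    sel <- grid_search_inner(data, tr, grid, inner_k,
                             seed = derive_seed(seed, "grid", f), positive)
    g <- sel$best
    str <- sub[match(tr, sub$subject_id), ]
    y_tr <- label_factor(str$label, positive)
    w <- compute_sample_weights(str$label, str$gender)
    x_tr <- extract_features(data, g, tr, tr)
    x_te <- extract_features(data, g, tr, te)
    model <- fit_classifier(x_tr, y_tr, w, g$classifier, g$params,
                            seed = derive_seed(seed, "refit", f))
    y_te <- sub$label[match(te, sub$subject_id)]
    pred <- as.character(predict(model, x_te))
    m_full <- metrics(y_te, pred, positive)
    m_sub <- rep(NA_real_, 4)
    if (matched) {
      ste <- sub[match(te, sub$subject_id), ]
      msub <- tryCatch(
        gender_match_subset(ste, seed = derive_seed(seed, "match", f)),
        error = function(e) {
          warning("fold ", f, ": ", conditionMessage(e), call. = FALSE)
          NULL
        })
      if (!is.null(msub)) {
        keep <- te %in% msub
        m_sub <- tryCatch(metrics(y_te[keep], pred[keep], positive),
                          error = function(e) rep(NA_real_, 4))
      }
    }
    rows[[f]] <- data.frame(
      fold = f, setup = setup_string(g), input_source = g$input_source,
      option = g$option, classifier = g$classifier,
      n_test = length(te),
      balanced_accuracy = m_full[["balanced_accuracy"]],
      f1 = m_full[["f1"]], precision = m_full[["precision"]],
      recall = m_full[["recall"]],
      matched_balanced_accuracy = m_sub[[1]], matched_f1 = m_sub[[2]],
      matched_precision = m_sub[[3]], matched_recall = m_sub[[4]],
      stringsAsFactors = FALSE
    )
  }
  structure(list(folds = do.call(rbind, rows), task = task, seed = seed,
                 plan = plan, grid = grid),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s vs %s, %d outer folds, seed %s\n",
              x$task[1], x$task[2], nrow(x$folds), x$seed))
  df <- x$folds
  show <- df[, intersect(c("fold", "modality", "setup", "balanced_accuracy",
                           "f1", "precision", "recall"), names(df))]
  for (cl in c("balanced_accuracy", "f1", "precision", "recall"))
    show[[cl]] <- sprintf("%.2f%%", 100 * show[[cl]])
  print(show, row.names = FALSE)
  s <- summary(x)
  cat(sprintf("mean balanced accuracy: %s\n",
              paste(sprintf("%s %.2f%% (%.2f%%)",
                            s$group, 100 * s$mean_balanced_accuracy,
                            100 * s$sd_balanced_accuracy), collapse = ", ")))
  invisible(x)
}

#' Summarise an evaluation report
#'
#' Arithmetic mean and standard deviation of every metric across the outer
#' test folds (per modality for stacked reports).
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return Data frame of per-group means and SDs.
#' @export
summary.evaluation_report <- function(object, ...) {
  df <- object$folds
  group <- if ("modality" %in% names(df)) df$modality else
    rep("overall", nrow(df))
  mets <- c("balanced_accuracy", "f1", "precision", "recall",
            "matched_balanced_accuracy")
  mets <- intersect(mets, names(df))
  out <- lapply(unique(group), function(g) {
    d <- df[group == g, , drop = FALSE]
    row <- list(group = g, n_folds = nrow(d))
    for (m in mets) {
      row[[paste0("mean_", m)]] <- mean(d[[m]], na.rm = TRUE)
      row[[paste0("sd_", m)]] <- stats::sd(d[[m]], na.rm = TRUE)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
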