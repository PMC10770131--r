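# Classifier registry: a uniform fit/predict-probability surface over the
# three classifier families used on the sensor and questionnaire features.
# Scale-sensitive learners (SVM, NN) get train-fold z-scoring; the
# gender-by-class sample weights enter every fit (aggregated to per-class
# weights for the SVM, whose implementation accepts class weights only).

#' Define one grid point (a fully specified trainable pipeline)
#'
#' @param input_source `"acceleration"`, `"rotation"`, `"both"` or
#'   `"questionnaire"`.
#' @param option Feature option: `"A"` (manual spectral/segment features),
#'   `"B"` (BOSS histograms) or `"Q"` (raw questionnaire answers).
#' @param classifier `"svm"`, `"gbt"` or `"nn"`.
#' @param params Named list of classifier hyperparameters (e.g. `cost`,
#'   `gamma` for the SVM; `nrounds`, `max_depth`, `eta` for the boosted
#'   trees; `size`, `decay` for the neural network; `windows`, `word_length`,
#'   `alphabet_size` for option B features).
#' @return An object of class `grid_point`.
#' @export
grid_point <- function(input_source, option = "A", classifier = "svm",
                       params = list()) {
  input_source <- match.arg(input_source,
                            c("acceleration", "rotation", "both",
                              "questionnaire"))
  option <- match.arg(option, c("A", "B", "Q"))
  classifier <- match.arg(classifier, c("svm", "gbt", "nn"))
  structure(list(input_source = input_source, option = option,
                 classifier = classifier, params = params),
            class = "grid_point")
}

#' @export
print.grid_point <- function(x, ...) {
  p <- if (length(x$params))
    paste0(" [", paste(names(x$params), unlist(x$params), sep = "=",
                       collapse = ", "), "]") else ""
  cat(sprintf("<grid_point> %s / option %s / %s%s\n",
              x$input_source, x$option, x$classifier, p))
  invisible(x)
}

#' Default hyperparameter grid
#'
#' A compact grid crossing input source, feature option and classifier. The
#' enumeration order is the deterministic tie-break order of the inner grid
#' search.
#'
#' @param input_sources Input sources to cross.
#' @param options Feature options to cross.
#' @param classifiers Classifier families to cross.
#' @return List of [grid_point()]s.
#' @export
default_grid <- function(input_sources = c("acceleration", "rotation", "both"),
                         options = "A",
                         classifiers = c("svm", "gbt")) {
  grid <- list()
  for (opt in options) for (src in input_sources) for (clf in classifiers) {
    params <- switch(clf,
                     svm = list(cost = 1),
                     gbt = list(nrounds = 50, max_depth = 3, eta = 0.3),
                     nn = list(size = 8, decay = 1e-3))
    grid[[length(grid) + 1L]] <- grid_point(src, opt, clf, params)
  }
  grid
}

standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

#' Fit one classifier on a feature matrix
#'
#' @param x Numeric feature matrix (subjects x features).
#' @param y Factor of class labels, second level = positive class.
#' @param weights Per-subject sample weights (see
#'   [compute_sample_weights()]).
#' @param classifier `"svm"`, `"gbt"` or `"nn"`.
#' @param params Hyperparameters (see [grid_point()]).
#' @param seed Seed controlling any stochastic element of the fit.
#' @return An object of class `watchpd_classifier` with a
#'   [predict][predict.watchpd_classifier] method.
#' @export
fit_classifier <- function(x, y, weights = rep(1, nrow(x)),
                           classifier = "svm", params = list(), seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("binary classification requires two classes",
                             call. = FALSE)
  positive <- levels(y)[2L]
  fit <- with_seed(seed, switch(
    classifier,
    svm = {
      std <- standardize_fit(x)
      cw <- tapply(weights, y, mean)
      model <- e1071::svm(standardize_apply(x, std), y,
                          kernel = "radial",
                          cost = params$cost %||% 1,
                          gamma = params$gamma %||% (1 / ncol(x)),
                          class.weights = cw, probability = TRUE)
      list(model = model, std = std)
    },
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y) - 1,
                                     weight = weights)
      model <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth %||% 3,
                      eta = params$eta %||% 0.3,
                      nthread = 1),
        data = dtrain, nrounds = params$nrounds %||% 50, verbose = 0)
      list(model = model)
    },
    nn = {
      std <- standardize_fit(x)
      xs <- standardize_apply(x, std)
      size <- params$size %||% 8
      model <- nnet::nnet(xs, as.numeric(y) - 1, size = size,
                          decay = params$decay %||% 1e-3,
                          weights = weights, entropy = TRUE, trace = FALSE,
                          maxit = params$maxit %||% 200,
                          MaxNWts = (ncol(x) + 2) * size + size + 10)
      list(model = model, std = std)
    },
    stop("unknown classifier: ", classifier, call. = FALSE)
  ))
  structure(list(classifier = classifier, fit = fit, levels = levels(y),
                 positive = positive, p = ncol(x)),
            class = "watchpd_classifier")
}

#' Predict labels or positive-class probabilities
#'
#' @param object A `watchpd_classifier`.
#' @param newdata Feature matrix with the training columns.
#' @param type `"class"` for labels, `"prob"` for positive-class
#'   probabilities.
#' @param ... Unused.
#' @export
predict.watchpd_classifier <- function(object, newdata,
                                       type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  prob <- switch(
    object$classifier,
    svm = {
      xs <- standardize_apply(newdata, object$fit$std)
      pr <- predict(object$fit$model, xs, probability = TRUE)
      attr(pr, "probabilities")[, object$positive]
    },
    gbt = predict(object$fit$model, xgboost::xgb.DMatrix(newdata)),
    nn = {
      xs <- standardize_apply(newdata, object$fit$std)
      as.numeric(predict(object$fit$model, xs))
    }
  )
  if (type == "prob") unname(prob)
  else factor(ifelse(prob >= 0.5, object$levels[2L], object$levels[1L]),
              levels = object$levels)
}
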