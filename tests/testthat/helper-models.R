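# A transparent linear test model: predicts PD when the weighted sum of the
# designated columns is positive. Lets importance properties be checked
# against a model whose dependence structure is known exactly.
linear_model <- function(cols, weights = rep(1, length(cols))) {
  structure(list(cols = cols, w = weights), class = "lin_test_model")
}
lin_predict <- function(model, x)
  ifelse(as.matrix(x[, model$cols, drop = FALSE]) %*% model$w > 0, "PD", "HC")
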