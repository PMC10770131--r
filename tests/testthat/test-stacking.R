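test_that("meta-features are out-of-fold, one row per subject, one column per sub-model", {
  data <- make_fake_data(n_per_class = 10, delta = 2, seed = 1,
                         quest_delta = 0.3)
  y <- watchpd:::label_factor(data$subjects$label, "PD")
  m <- fit_stack(data$manual, data$questionnaire, y, inner_k = 5, seed = 2,
                 sensor_spec = grid_point("acceleration", "A", "svm"),
                 quest_spec = grid_point("questionnaire", "Q", "gbt"))
  expect_s3_class(m, "stacked_model")
  expect_equal(dim(m$meta_features), c(20, 2))
  expect_equal(colnames(m$meta_features), c("sensor", "questionnaire"))
  expect_false(anyNA(m$meta_features))
  expect_equal(sort(unique(m$meta_folds)), 1:5)
  expect_output(print(m), "meta coefficients")
})

test_that("prediction requires both modalities and is order-equivariant", {
  data <- make_fake_data(n_per_class = 10, delta = 2, seed = 3,
                         quest_delta = 0.3)
  y <- watchpd:::label_factor(data$subjects$label, "PD")
  m <- fit_stack(data$manual, data$questionnaire, y, inner_k = 4, seed = 2)
  expect_error(predict(m, list(sensor = data$manual)),
               "missing modality 'questionnaire'")
  p <- predict(m, list(sensor = data$manual,
                       questionnaire = data$questionnaire), type = "prob")
  expect_true(all(p >= 0 & p <= 1))
  rev_idx <- rev(seq_len(nrow(data$manual)))
  p_rev <- predict(m, list(sensor = data$manual[rev_idx, ],
                           questionnaire = data$questionnaire[rev_idx, ]),
                   type = "prob")
  expect_equal(p_rev, p[rev_idx])
})

test_that("stacking a perfect and a random modality tracks the perfect one", {
  # sensor features fully separate the classes; questionnaire is coin flips
  data <- make_fake_data(n_per_class = 14, delta = 4, seed = 4,
                         quest_delta = 0)
  train <- data$subjects$subject_id[c(1:10, 15:24)]
  test <- setdiff(data$subjects$subject_id, train)
  ytr <- watchpd:::label_factor(
    data$subjects$label[match(train, data$subjects$subject_id)], "PD")
  m <- fit_stack(data$manual[train, ], data$questionnaire[train, ], ytr,
                 inner_k = 4, seed = 5)
  yte <- data$subjects$label[match(test, data$subjects$subject_id)]
  pred_stack <- as.character(predict(
    m, list(sensor = data$manual[test, ],
            questionnaire = data$questionnaire[test, ])))
  pred_quest <- as.character(predict(m$submodels$questionnaire,
                                     data$questionnaire[test, ]))
  ba_stack <- metrics(yte, pred_stack)[["balanced_accuracy"]]
  ba_quest <- metrics(yte, pred_quest)[["balanced_accuracy"]]
  expect_gte(ba_stack, ba_quest)
  expect_gte(ba_stack, 0.9)                # within noise of the perfect one
})

test_that("identical modalities stack to single-modality performance", {
  data <- make_fake_data(n_per_class = 12, delta = 2, seed = 6)
  x <- data$manual
  y <- watchpd:::label_factor(data$subjects$label, "PD")
  m <- fit_stack(x, x, y, inner_k = 4, seed = 7,
                 sensor_spec = grid_point("acceleration", "A", "gbt"),
                 quest_spec = grid_point("questionnaire", "Q", "gbt"))
  p_single <- as.character(predict(m$submodels$sensor, x))
  p_stack <- as.character(predict(m, list(sensor = x, questionnaire = x)))
  ba_single <- metrics(data$subjects$label, p_single)[["balanced_accuracy"]]
  ba_stack <- metrics(data$subjects$label, p_stack)[["balanced_accuracy"]]
  expect_lt(abs(ba_stack - ba_single), 0.15)
})

test_that("evaluate_stack reports sensor, questionnaire and stacked rows", {
  data <- make_fake_data(n_per_class = 12, delta = 3, seed = 8,
                         quest_delta = 0.35)
  rep1 <- evaluate_stack(data, c("PD", "HC"),
                         sensor_grid = list(grid_point("acceleration", "A",
                                                       "svm")),
                         outer_k = 3, inner_k = 3, seed = 9, matched = FALSE)
  expect_equal(nrow(rep1$folds), 9)
  expect_equal(sort(unique(rep1$folds$modality)),
               c("questionnaire", "sensor", "stacked"))
  s <- summary(rep1)
  expect_equal(sort(s$group), c("questionnaire", "sensor", "stacked"))
  rep2 <- evaluate_stack(data, c("PD", "HC"),
                         sensor_grid = list(grid_point("acceleration", "A",
                                                       "svm")),
                         outer_k = 3, inner_k = 3, seed = 9, matched = FALSE)
  expect_identical(rep1$folds, rep2$folds)
})
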