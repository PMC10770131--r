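test_that("cv plans are stratified, disjoint and seed-deterministic", {
  ids <- sprintf("s%02d", 1:10)
  labels <- rep(c("PD", "HC"), each = 5)
  plan <- make_cv_plan(ids, labels, outer_k = 5, seed = 3)
  expect_equal(as.vector(table(plan$assignment$fold)), rep(2, 5))
  expect_setequal(plan$assignment$subject_id, ids)
  # each fold holds one subject per class
  tab <- table(plan$assignment$label, plan$assignment$fold)
  expect_true(all(tab == 1))
  expect_identical(make_cv_plan(ids, labels, outer_k = 5, seed = 3), plan)
  expect_false(identical(make_cv_plan(ids, labels, outer_k = 5, seed = 4),
                         plan))
})

test_that("fold class ratios stay within one subject of the cohort ratio", {
  set.seed(6)
  ids <- sprintf("s%03d", 1:100)
  labels <- rep(c("A", "B"), times = c(60, 40))
  plan <- make_cv_plan(ids, labels, outer_k = 5, seed = 8)
  tab <- table(plan$assignment$label, plan$assignment$fold)
  expect_true(all(abs(tab["A", ] - 12) <= 1))
  expect_true(all(abs(tab["B", ] - 8) <= 1))
})

test_that("cv plan rejects impossible stratification and duplicates", {
  expect_error(make_cv_plan(c("a", "b", "c"), c("PD", "PD", "HC"),
                            outer_k = 2),
               "fewer subjects than folds")
  expect_error(make_cv_plan(c("a", "a"), c("PD", "HC")), "unique")
  expect_error(make_cv_plan("a", c("PD", "HC")), "equal length")
})

test_that("gender-by-class weights follow w = N / (G * n_g)", {
  labels <- rep(c("PD", "HC"), each = 4)
  genders <- rep(c("male", "female"), times = 4)
  expect_equal(compute_sample_weights(labels, genders), rep(1, 8))

  labels2 <- rep("PD", 40)
  genders2 <- rep(c("male", "female"), times = c(30, 10))
  w <- compute_sample_weights(labels2, genders2)
  expect_equal(unique(w[genders2 == "male"]), 40 / (2 * 30))
  expect_equal(unique(w[genders2 == "female"]), 40 / (2 * 10))
  # every non-empty group carries mass N / G
  expect_equal(sum(w[genders2 == "male"]), 20)
  expect_equal(sum(w[genders2 == "female"]), 20)
  expect_error(compute_sample_weights(character(0), character(0)), "empty")
})

test_that("metric suite matches hand-computed confusion matrices", {
  perfect <- metrics(c("PD", "PD", "HC"), c("PD", "PD", "HC"))
  expect_equal(unname(perfect), c(1, 1, 1, 1))

  # constant positive predictor on imbalanced truth
  y <- rep(c("PD", "HC"), times = c(9, 1))
  m <- metrics(y, rep("PD", 10))
  expect_equal(m[["balanced_accuracy"]], 0.5)

  y_true <- c(1, 1, 1, 0, 0)
  y_pred <- c(1, 1, 0, 0, 1)
  m2 <- metrics(y_true, y_pred, positive = "1")
  expect_equal(m2[["balanced_accuracy"]], (2 / 3 + 1 / 2) / 2)
  expect_equal(m2[["precision"]], 2 / 3)
  expect_equal(m2[["recall"]], 2 / 3)
  expect_equal(m2[["f1"]], 2 / 3)

  expect_error(metrics(rep("PD", 5), rep("PD", 5)), "class absent")
  expect_error(metrics(c("PD", "HC"), "PD"), "equal length")
})

test_that("balanced accuracy is swap-invariant and equals accuracy when balanced", {
  set.seed(7)
  y <- rep(c("PD", "HC"), each = 20)
  p <- sample(c("PD", "HC"), 40, replace = TRUE)
  m1 <- metrics(y, p)[["balanced_accuracy"]]
  swap <- function(v) ifelse(v == "PD", "HC", "PD")
  m2 <- metrics(swap(y), swap(p))[["balanced_accuracy"]]
  expect_equal(m1, m2)
  # balanced classes with balanced predictions per class count
  y2 <- rep(c("PD", "HC"), each = 10)
  p2 <- c(rep("PD", 7), rep("HC", 3), rep("HC", 7), rep("PD", 3))
  expect_equal(metrics(y2, p2)[["balanced_accuracy"]], mean(y2 == p2))
})

test_that("gender matching equalises gender ratios across classes", {
  subj <- data.frame(
    subject_id = sprintf("s%02d", 1:16),
    label = rep(c("PD", "HC"), each = 8),
    gender = c(rep("male", 6), rep("female", 2),
               rep("male", 2), rep("female", 6)),
    stringsAsFactors = FALSE)
  keep <- gender_match_subset(subj, seed = 5)
  sel <- subj[subj$subject_id %in% keep, ]
  tab <- table(sel$gender, sel$label)
  expect_true(all(tab == 2))                # min cell per gender is 2
  expect_identical(gender_match_subset(subj, seed = 5), keep)

  balanced <- data.frame(
    subject_id = sprintf("b%02d", 1:8),
    label = rep(c("PD", "HC"), each = 4),
    gender = rep(c("male", "female"), times = 4),
    stringsAsFactors = FALSE)
  expect_setequal(gender_match_subset(balanced, seed = 1),
                  balanced$subject_id)

  broken <- subj[subj$gender == "female" | subj$label == "PD", ]
  expect_error(gender_match_subset(broken, seed = 1),
               "empty gender-by-class cell")
  expect_error(gender_match_subset(data.frame(subject_id = "a", label = "PD",
                                              gender = "male")),
               "two classes")
})
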