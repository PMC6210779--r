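test_that("stratified split preserves class composition and is seeded", {
  labels <- c(rep("FoG", 36), rep("noFoG", 15))
  sp <- stratified_split(labels, train_fraction = 0.7, seed = 3)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), 1:51)
  # per-class half-up rounding: 25 + 11 train, 11 + 4 validation
  expect_equal(sum(labels[sp$train] == "FoG"), 25)
  expect_equal(sum(labels[sp$train] == "noFoG"), 11)
  expect_length(sp$train, 36)
  expect_length(sp$validation, 15)

  # same seed -> identical split; different seed -> (almost surely) not
  expect_identical(stratified_split(labels, seed = 3), sp)
  expect_false(identical(stratified_split(labels, seed = 4)$train, sp$train))

  # 50:50 on a balanced cohort
  lab2 <- rep(c("FoG", "noFoG"), each = 10)
  sp2 <- stratified_split(lab2, train_fraction = 0.5, seed = 1)
  expect_equal(sum(lab2[sp2$train] == "FoG"), 5)
  expect_equal(sum(lab2[sp2$train] == "noFoG"), 5)

  expect_error(stratified_split(c("FoG", "FoG", "noFoG"), seed = 1),
               "stratification error")
  expect_error(stratified_split(rep("FoG", 10), seed = 1),
               "stratification error")
})

test_that("classifiers separate well-separated clouds and reject bad input", {
  set.seed(8)
  x <- rbind(matrix(rnorm(40 * 5, 0), ncol = 5),
             matrix(rnorm(40 * 5, 6), ncol = 5))
  colnames(x) <- paste0("f", 1:5)
  y <- rep(c("noFoG", "FoG"), each = 40)
  for (kind in c("svm_rbf", "knn", "dt", "nb")) {
    m <- train_classifier(x, y, kind = kind, seed = 1)
    ev <- evaluate(m, x, y)
    expect_equal(ev$accuracy, 100)
  }
  expect_error(train_classifier(x, y, kind = "rf"), "parameter error")
  expect_error(train_classifier(x, rep("FoG", 80), kind = "svm_rbf"),
               "degenerate|class")

  # all-identical rows: the model falls back to the majority class
  xc <- matrix(1, nrow = 10, ncol = 3)
  colnames(xc) <- paste0("f", 1:3)
  yc <- c(rep("FoG", 7), rep("noFoG", 3))
  mc <- train_classifier(xc, yc, kind = "svm_rbf", seed = 1)
  expect_true(all(predict(mc, xc) == "FoG"))
})

test_that("evaluation metrics follow the confusion-matrix formulas", {
  set.seed(8)
  x <- rbind(matrix(rnorm(20 * 3, 0), ncol = 3),
             matrix(rnorm(20 * 3, 6), ncol = 3))
  colnames(x) <- paste0("f", 1:3)
  y <- rep(c("noFoG", "FoG"), each = 20)
  m <- train_classifier(x, y, kind = "knn", seed = 1)
  ev <- evaluate(m, x, y)
  expect_equal(ev$sensitivity, 100)
  expect_equal(ev$specificity, 100)
  expect_equal(sum(ev$confusion), 40)

  # recomputing from the returned confusion matrix matches the percentages
  cm <- ev$confusion
  expect_equal(ev$accuracy,
               100 * (cm[["TP"]] + cm[["TN"]]) / sum(cm), tolerance = 1e-9)

  # the 32-of-36 sensitivity case: 32 / 36 = 88.89%
  fake <- structure(list(kind = "knn",
                         fit = list(majority = "FoG"),
                         center = c(f1 = 0), scale = c(f1 = 1),
                         levels = c("noFoG", "FoG")),
                    class = "fog_model")
  xx <- matrix(rnorm(51), ncol = 1, dimnames = list(NULL, "f1"))
  yy <- c(rep("FoG", 36), rep("noFoG", 15))
  # majority model predicts all FoG: TP=36; flip 4 labels to get TP=32, FN=4
  ev2 <- evaluate(fake, xx[1:36, , drop = FALSE],
                  c(rep("FoG", 32), rep("noFoG", 4)))
  expect_equal(ev2$confusion[["TP"]], 32)
  # sensitivity computed on a set with 32 TP / 4 FN
  ev3 <- evaluate(fake, xx, c(rep("FoG", 36), rep("noFoG", 15)))
  expect_equal(ev3$sensitivity, 100)
  expect_equal(round(100 * 32 / 36, 2), 88.89)

  # zero-denominator metrics are NA, not 0
  ev4 <- evaluate(fake, xx[1:5, , drop = FALSE], rep("noFoG", 5))
  expect_true(is.na(ev4$sensitivity))
  expect_equal(ev4$specificity, 0)
  expect_error(evaluate(fake, xx[0, , drop = FALSE], character()), "empty")
})

test_that("report aggregation is the arithmetic mean of simulations", {
  acc <- c(85.71, 88.57, 88.57, 91.42, 88.57, 88.57, 91.42, 88.57, 88.57,
           91.42)
  rep1 <- classification_report(
    "svm_rbf",
    tibble::tibble(accuracy = acc, sensitivity = acc, specificity = acc)
  )
  expect_equal(rep1$mean_accuracy, 89.139, tolerance = 1e-9)
  single <- classification_report(
    "nb", tibble::tibble(accuracy = 80, sensitivity = 75, specificity = 90)
  )
  expect_equal(single$mean_accuracy, 80)
})

test_that("repeated simulations are reproducible and leakage-free", {
  coh <- simulate_feature_cohort(20, 16, effect_size = 2, seed = 12)
  r1 <- run_simulations(coh, coh$label, kinds = c("svm_rbf", "nb"),
                        n_simulations = 3, base_seed = 5)
  r2 <- run_simulations(coh, coh$label, kinds = c("svm_rbf", "nb"),
                        n_simulations = 3, base_seed = 5)
  expect_identical(tidy(r1), tidy(r2))
  expect_equal(names(r1), c("svm_rbf", "nb"))
  expect_true(all(tidy(r1)$accuracy >= 0 & tidy(r1)$accuracy <= 100))
  # means match the per-simulation rows
  expect_equal(r1$svm_rbf$mean_accuracy,
               mean(r1$svm_rbf$per_simulation$accuracy), tolerance = 1e-12)
  expect_error(run_simulations(coh, coh$label, n_simulations = 0),
               "parameter error")
})

test_that("a balanced null cohort scores at chance for every classifier", {
  # with no class effect, mean validation accuracy must sit inside the
  # central 99% binomial band around 50%
  coh <- simulate_feature_cohort(26, 26, effect_size = 0, seed = 5)
  reps <- run_simulations(coh, coh$label, n_simulations = 10, base_seed = 7)
  n_eval <- 16 * 10   # validation fold size x simulations
  half_width <- stats::qnorm(0.995) * sqrt(0.25 / n_eval) * 100
  for (k in names(reps)) {
    expect_gt(reps[[k]]$mean_accuracy, 50 - half_width)
    expect_lt(reps[[k]]$mean_accuracy, 50 + half_width)
  }
})

test_that("a strongly separated cohort is classified almost perfectly", {
  coh <- simulate_feature_cohort(36, 15, effect_size = 3, seed = 5)
  reps <- run_simulations(coh, coh$label, kinds = "svm_rbf",
                          n_simulations = 10, base_seed = 7)
  expect_gte(reps$svm_rbf$mean_accuracy, 95)
})
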