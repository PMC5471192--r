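# Classifier protocol: splits, cross-validation, confusion, ROC, curves.

test_that("stratified splits are exact, deterministic and handle odd sizes", {
  tbl <- make_toy_table(n_per_class = 100)
  sp <- split_train_test(tbl, 0.5, seed = 3)
  expect_equal(unname(table(sp$train$class)), rep(50L, 5), ignore_attr = TRUE)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(tbl))
  expect_equal(length(intersect(sp$train$object_id, sp$test$object_id)), 0)
  sp2 <- split_train_test(tbl, 0.5, seed = 3)
  expect_identical(sort(sp$train$object_id), sort(sp2$train$object_id))

  odd <- make_toy_table(n_per_class = 11)
  spo <- split_train_test(odd, 0.5, seed = 1)
  expect_true(all(table(spo$train$class) == 5))
  expect_true(all(table(spo$test$class) == 6))
  expect_error(split_train_test(tbl, 1.2, seed = 1), "fraction")
  one <- tbl[c(1, 101, 201, 301, 401), ]
  expect_error(split_train_test(one, 0.5, seed = 1), "fewer than 2")
})

test_that("perfectly separated classes are classified perfectly by every method", {
  # five classes at the corners of a pentagon, 15 noise-sds apart
  set.seed(12)
  n <- 30
  ang <- 2 * pi * (1:5) / 5
  tbl <- tibble::tibble(
    f1 = rep(15 * cos(ang), each = n) + rnorm(5 * n),
    f2 = rep(15 * sin(ang), each = n) + rnorm(5 * n),
    class = rep(phenotype_levels(), each = n),
    image_id = "sep", object_id = seq_len(5 * n)
  )
  for (m in names(default_classifiers())) {
    cv <- cross_validate(classifier_spec(m), tbl, k = 5, seed = 1)
    expect_equal(cv$overall, 100, info = m)
  }
})

test_that("permuted labels give chance-level accuracy for the random forest", {
  tbl <- make_toy_table(n_per_class = 50, p = 10, sep = 3)
  accs <- numeric(10)
  for (r in 1:10) {
    set.seed(1000 + r)
    shuf <- tbl
    shuf$class <- sample(shuf$class)
    accs[r] <- cross_validate(classifier_spec("random_forest"), shuf,
                              k = 10, seed = r)$overall
  }
  expect_gt(mean(accs), 15)
  expect_lt(mean(accs), 25)
})

test_that("leave-one-out 1-NN on duplicated points is perfect", {
  base <- make_toy_table(n_per_class = 4, sep = 4, seed = 2)
  dup <- dplyr::bind_rows(base, base)
  dup$object_id <- seq_len(nrow(dup))
  cv <- cross_validate(classifier_spec("knn", k = 1), dup, k = 8, seed = 1)
  expect_equal(cv$overall, 100)
})

test_that("the in-package kNN agrees with class::knn on hard labels", {
  skip_if_not_installed("class")
  tbl <- make_toy_table(n_per_class = 40, sep = 1.2, seed = 5)
  sp <- split_train_test(tbl, 0.5, seed = 2)
  model <- fit_classifier(classifier_spec("knn", k = 1), sp$train)
  mine <- as.character(predict_cells(model, sp$test)$.pred)
  xs_tr <- cytoprofiler:::standardizer_apply(model$std,
    as.matrix(sp$train[, model$features]))
  xs_te <- cytoprofiler:::standardizer_apply(model$std,
    as.matrix(sp$test[, model$features]))
  ref <- as.character(class::knn(xs_tr, xs_te, factor(sp$train$class), k = 1))
  expect_equal(mine, ref)
})

test_that("confusion matrices are row percentages with the declared layout", {
  truth <- rep(phenotype_levels(), each = 4)
  cm <- confusion_matrix_percent(truth, truth)
  expect_equal(unname(diag(cm)), rep(100, 5))
  all_m1 <- confusion_matrix_percent(truth, rep("M1", 20))
  expect_equal(unname(all_m1[, "M1"]), rep(100, 5))
  set.seed(4)
  pred <- sample(phenotype_levels(), 20, replace = TRUE)
  cm2 <- confusion_matrix_percent(truth, pred)
  expect_true(all(abs(rowSums(cm2) - 100) <= 0.1))
  expect_error(confusion_matrix_percent(truth, c(pred[-1], "weird")), "unseen")
})

test_that("overall accuracy is the class-size-weighted mean of per-class accuracy", {
  tbl <- make_toy_table(n_per_class = 30, sep = 1)
  cv <- cross_validate(classifier_spec("naive_bayes"), tbl, k = 5, seed = 2)
  weighted <- sum(cv$per_class$accuracy * cv$per_class$n) / sum(cv$per_class$n)
  expect_equal(cv$overall, weighted, tolerance = 1e-9)
})

test_that("one-vs-rest ROC handles the canonical score patterns", {
  truth <- rep(c("M1", "M2"), each = 10)
  onehot <- cbind(M1 = as.numeric(truth == "M1"), M2 = as.numeric(truth == "M2"))
  r <- roc_one_vs_rest(onehot, truth)
  expect_equal(unname(r$auc["M1"]), 1)
  const <- cbind(M1 = rep(0.5, 20), M2 = rep(0.5, 20))
  expect_equal(unname(roc_one_vs_rest(const, truth)$auc["M1"]), 0.5)
  inverted <- cbind(M1 = as.numeric(truth != "M1"), M2 = as.numeric(truth != "M2"))
  expect_equal(unname(roc_one_vs_rest(inverted, truth)$auc["M1"]), 0)
  expect_error(roc_one_vs_rest(onehot, rep("M1", 20)), "two classes")
  # curves are monotone staircases from (0,0) to (1,1)
  set.seed(6)
  sc <- cbind(M1 = runif(20), M2 = runif(20))
  rr <- roc_one_vs_rest(sc, truth)
  for (cl in c("M1", "M2")) {
    cv <- rr$curves[rr$curves$class == cl, ]
    expect_true(all(diff(cv$fpr) >= 0))
    expect_true(all(diff(cv$tpr) >= 0))
    expect_equal(range(cv$fpr), c(0, 1))
  }
})

test_that("trapezoidal AUC matches pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(11)
  truth <- sample(c("M1", "M2"), 60, replace = TRUE)
  scores <- cbind(M1 = runif(60), M2 = runif(60))
  mine <- roc_one_vs_rest(scores, truth)$auc["M1"]
  ref <- suppressMessages(pROC::auc(pROC::roc(truth == "M1", scores[, "M1"],
                                              direction = "<", quiet = TRUE)))
  expect_equal(unname(mine), as.numeric(ref), tolerance = 1e-9)
})

test_that("standardization statistics come from the training partition only", {
  tbl <- make_toy_table(n_per_class = 30)
  sp <- split_train_test(tbl, 0.5, seed = 1)
  model <- fit_classifier(classifier_spec("naive_bayes"), sp$train)
  x_train <- as.matrix(sp$train[, model$features])
  expect_equal(unname(model$std$center), unname(colMeans(x_train)), tolerance = 1e-12)
  x_all <- as.matrix(tbl[, model$features])
  expect_gt(max(abs(model$std$center - colMeans(x_all))), 0)
})

test_that("learning curves are deterministic and consistent with a split evaluation", {
  tbl <- make_toy_table(n_per_class = 40, sep = 1.5)
  lc1 <- learning_curve(classifier_spec("naive_bayes"), tbl,
                        fractions = 0.5, repeats = 1, seed = 9)
  lc2 <- learning_curve(classifier_spec("naive_bayes"), tbl,
                        fractions = 0.5, repeats = 1, seed = 9)
  expect_identical(lc1, lc2)
  lc <- learning_curve(classifier_spec("random_forest"), tbl,
                       fractions = c(0.1, 0.6), repeats = 2, seed = 4)
  expect_gte(lc$mean_accuracy[lc$fraction == 0.6],
             lc$mean_accuracy[lc$fraction == 0.1] - 5)
  expect_error(learning_curve(classifier_spec("knn"), tbl, fractions = 1.5),
               "fractions")
})

test_that("blind prediction is consistent and validates its schema", {
  tbl <- make_toy_table(n_per_class = 25, sep = 4)
  model <- fit_classifier(classifier_spec("random_forest"), tbl)
  blind <- predict_blind(model, tbl)
  resub <- predict_cells(model, tbl)
  expect_identical(blind$.pred, resub$.pred)
  empty <- tbl[0, ]
  expect_equal(nrow(predict_blind(model, empty)), 0)
  broken <- tbl[, -4]
  expect_error(predict_cells(model, broken), "missing training column")
})

test_that("evaluation reports tidy into per-class and per-classifier summaries", {
  tbl <- make_toy_table(n_per_class = 30, sep = 2)
  ev <- evaluate_classifiers(tbl,
                             classifiers = default_classifiers()[c("random_forest", "naive_bayes")],
                             folds = 5, seed = 2)
  td <- tidy(ev)
  expect_setequal(unique(td$protocol), c("cv", "holdout"))
  expect_equal(nrow(td), 2 * 2 * 5)
  gl <- glance(ev)
  expect_equal(gl$classifier, c("random_forest", "naive_bayes"))
  expect_true(all(gl$mean_auc >= 0 & gl$mean_auc <= 1))
  expect_s3_class(autoplot(ev, "accuracy"), "ggplot")
  expect_s3_class(autoplot(ev, "confusion"), "ggplot")
  expect_s3_class(autoplot(ev, "roc"), "ggplot")
})
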