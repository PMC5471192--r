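# The five supervised classifiers behind a single fit/predict surface.
#
# All methods see features standardized to zero mean / unit variance using
# statistics computed on the training partition only; the same statistics are
# re-applied at prediction time (no test-set leakage).

#' Specify one of the five supervised classifiers
#'
#' @param method One of `"random_forest"`, `"logistic_regression"`, `"svm"`,
#'   `"knn"`, `"naive_bayes"`.
#' @param n_trees Random forest: number of trees.
#' @param k k-nearest neighbours: neighbourhood size.
#' @param kernel,cost SVM kernel and soft-margin cost.
#' @param lambda Ridge penalty of the one-vs-rest logistic regression.
#' @param rng_seed Seed used for any stochastic fitting step.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(method = c("random_forest", "logistic_regression",
                                       "svm", "knn", "naive_bayes"),
                            n_trees = 20, k = 5, kernel = "radial", cost = 1,
                            lambda = 0.001, rng_seed = 1) {
  method <- match.arg(method)
  if (n_trees < 1) abort("n_trees must be >= 1")
  if (k < 1) abort("k must be >= 1")
  structure(list(method = method, n_trees = as.integer(n_trees),
                 k = as.integer(k), kernel = kernel, cost = cost,
                 lambda = lambda, rng_seed = as.integer(rng_seed)),
            class = "classifier_spec")
}

#' The paper-protocol set of five classifier specifications
#' @param rng_seed Shared seed.
#' @return Named list of [classifier_spec()] objects.
#' @export
default_classifiers <- function(rng_seed = 1) {
  list(
    random_forest = classifier_spec("random_forest", rng_seed = rng_seed),
    logistic_regression = classifier_spec("logistic_regression", rng_seed = rng_seed),
    svm = classifier_spec("svm", rng_seed = rng_seed),
    knn = classifier_spec("knn", rng_seed = rng_seed),
    naive_bayes = classifier_spec("naive_bayes", rng_seed = rng_seed)
  )
}

feature_columns <- function(table) {
  setdiff(names(table), c("image_id", "object_id", "class"))
}

table_xy <- function(table) {
  x <- as.matrix(table[, feature_columns(table)])
  y <- factor(table$class, levels = intersect(phenotype_levels(),
                                              unique(table$class)))
  list(x = x, y = y)
}

standardizer_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd_pop)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

standardizer_apply <- function(std, x) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

#' Train one classifier on a labelled feature table
#'
#' @param spec A [classifier_spec()].
#' @param table Labelled feature table (rows = cells, 228 feature columns
#'   plus `class`).
#' @param probabilities Fit the probability model where it costs extra
#'   (SVM); per-class scores are then available from [predict_cells()].
#' @return A `cyto_model` object.
#' @export
fit_classifier <- function(spec, table, probabilities = TRUE) {
  stopifnot(inherits(spec, "classifier_spec"))
  d <- table_xy(table)
  std <- standardizer_fit(d$x)
  xs <- standardizer_apply(std, d$x)
  set.seed(spec$rng_seed)
  fit <- switch(
    spec$method,
    random_forest = randomForest::randomForest(x = xs, y = d$y,
                                               ntree = spec$n_trees),
    logistic_regression = lapply(setNames(levels(d$y), levels(d$y)), function(cl) {
      glmnet::glmnet(xs, factor(d$y == cl, levels = c(FALSE, TRUE)),
                     family = "binomial", alpha = 0, maxit = 5e5,
                     lambda = spec$lambda * c(100, 10, 1))
    }),
    svm = e1071::svm(x = xs, y = d$y, kernel = spec$kernel, cost = spec$cost,
                     probability = probabilities),
    knn = list(x = xs, y = d$y),
    naive_bayes = e1071::naiveBayes(x = xs, y = d$y)
  )
  structure(list(spec = spec, std = std, fit = fit, levels = levels(d$y),
                 features = feature_columns(table)),
            class = "cyto_model")
}

# per-class k-NN vote fractions (Euclidean, standardized features);
# distance ties resolved by stable ordering, label ties by class order
knn_scores <- function(train_x, train_y, test_x, k) {
  lv <- levels(train_y)
  tn2 <- rowSums(train_x^2)
  out <- matrix(0, nrow(test_x), length(lv), dimnames = list(NULL, lv))
  for (i in seq_len(nrow(test_x))) {
    d2 <- tn2 - 2 * as.vector(train_x %*% test_x[i, ]) + sum(test_x[i, ]^2)
    nb <- order(d2)[seq_len(min(k, length(d2)))]
    tab <- table(factor(train_y[nb], levels = lv))
    out[i, ] <- as.numeric(tab) / length(nb)
  }
  out
}

#' Predict phenotype labels and per-class scores
#'
#' @param model A `cyto_model` from [fit_classifier()].
#' @param table Feature table with the training feature columns (a class
#'   column is not required).
#' @return Tibble with `.pred` (factor label; score ties resolved toward the
#'   first class in canonical order) and one `.score_<class>` column per
#'   class.
#' @export
predict_cells <- function(model, table) {
  missing <- setdiff(model$features, names(table))
  if (length(missing)) {
    abort(paste0("feature table is missing training column(s): ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) " ..."))
  }
  lv <- model$levels
  if (!nrow(table)) {
    out <- tibble(.pred = factor(character(), levels = lv))
    for (cl in lv) out[[paste0(".score_", cl)]] <- numeric(0)
    return(out)
  }
  x <- as.matrix(table[, model$features])
  xs <- standardizer_apply(model$std, x)
  spec <- model$spec
  scores <- switch(
    spec$method,
    random_forest = predict(model$fit, xs, type = "prob"),
    logistic_regression = {
      s <- vapply(lv, function(cl) {
        as.vector(predict(model$fit[[cl]], xs, s = spec$lambda,
                          type = "response"))
      }, numeric(nrow(xs)))
      s <- matrix(s, nrow = nrow(xs), dimnames = list(NULL, lv))
      sweep(s, 1, pmax(rowSums(s), 1e-12), "/")
    },
    svm = {
      if (isTRUE(model$fit$compprob)) {
        p <- predict(model$fit, xs, probability = TRUE)
        attr(p, "probabilities")[, lv, drop = FALSE]
      } else {
        p <- predict(model$fit, xs)  # hard labels as one-hot scores
        m <- matrix(0, nrow(xs), length(lv), dimnames = list(NULL, lv))
        m[cbind(seq_len(nrow(xs)), match(as.character(p), lv))] <- 1
        m
      }
    },
    knn = knn_scores(model$fit$x, model$fit$y, xs, spec$k),
    naive_bayes = {
      pr <- predict(model$fit, xs, type = "raw", threshold = 1e-3, eps = 1e-9)
      pr[, lv, drop = FALSE]
    }
  )
  scores <- matrix(as.numeric(scores), nrow = nrow(xs),
                   dimnames = list(NULL, colnames(scores)))
  scores <- scores[, lv, drop = FALSE]
  pred <- factor(lv[apply(scores, 1, which.max)], levels = lv)
  out <- tibble(.pred = pred)
  for (cl in lv) out[[paste0(".score_", cl)]] <- scores[, cl]
  out
}
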