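# Evaluation protocol: stratified split, 10-fold CV, row-percentage confusion
# matrices, one-vs-rest ROC, learning curves.

#' Stratified train/test split
#'
#' Per class, `floor(fraction * n)` rows go to the training set; the halves
#' are disjoint and their union is the input table.
#'
#' @param table Labelled feature table.
#' @param fraction Training proportion in (0, 1).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_train_test <- function(table, fraction = 0.5, seed = 1) {
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  counts <- table(table$class)
  if (any(counts < 2)) {
    abort(paste0("class(es) with fewer than 2 rows: ",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  set.seed(seed)
  take <- logical(nrow(table))
  for (cl in names(counts)) {
    idx <- which(table$class == cl)
    take[sample(idx, floor(fraction * length(idx)))] <- TRUE
  }
  list(train = table[take, ], test = table[!take, ])
}

#' Row-percentage confusion matrix
#'
#' Entry (i, j) is the percentage of true-class-i cells predicted as class j;
#' every row sums to 100. Per-class accuracy (recall) is the diagonal.
#'
#' @param truth,pred Vectors of true and predicted labels over the same
#'   class set.
#' @param levels Class order; defaults to the canonical phenotype order
#'   restricted to the labels present.
#' @return Numeric matrix with class dimnames.
#' @export
confusion_matrix_percent <- function(truth, pred,
                                     levels = intersect(phenotype_levels(),
                                                        unique(c(truth, pred)))) {
  truth <- as.character(truth); pred <- as.character(pred)
  bad <- setdiff(unique(c(truth, pred)), levels)
  if (length(bad)) abort(paste0("unseen label(s): ", paste(bad, collapse = ", ")))
  tab <- table(factor(truth, levels), factor(pred, levels))
  sweep(unclass(tab), 1, pmax(rowSums(tab), 1), "/") * 100
}

accuracy_from_predictions <- function(truth, pred, levels) {
  cm <- confusion_matrix_percent(truth, pred, levels)
  tibble(class = levels, accuracy = diag(cm),
         n = as.integer(table(factor(truth, levels))))
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Per-class accuracy is the pooled recall over all folds (correctly
#' classified members of the class divided by the class size); the overall
#' accuracy is the class-size-weighted mean, i.e. the pooled fraction
#' correct. Deterministic given `seed`.
#'
#' @param spec A [classifier_spec()].
#' @param table Labelled feature table; every class needs >= k rows.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fitting.
#' @param scores Keep pooled per-class scores (needed for ROC on CV
#'   predictions; costs an extra probability model for the SVM).
#' @return List: `per_class` (tibble class/accuracy/n), `overall` (%),
#'   `confusion` (row-percentage matrix), `predictions` (tibble with truth,
#'   .pred and, if requested, score columns).
#' @export
cross_validate <- function(spec, table, k = 10, seed = 1, scores = FALSE) {
  if (k < 2) abort("k must be >= 2")
  counts <- table(table$class)
  if (any(counts < k)) {
    abort(paste0("every class needs at least k rows; short: ",
                 paste(names(counts)[counts < k], collapse = ", ")))
  }
  lv <- intersect(phenotype_levels(), unique(table$class))
  fold <- stratified_folds(table$class, k, seed)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- table[fold != f, ]
    test <- table[fold == f, ]
    spec_f <- spec; spec_f$rng_seed <- spec$rng_seed + f
    model <- fit_classifier(spec_f, train, probabilities = scores)
    p <- predict_cells(model, test)
    p$truth <- test$class
    p$row <- which(fold == f)
    preds[[f]] <- p
  }
  pooled <- bind_rows(preds)
  pooled <- pooled[order(pooled$row), ]
  per_class <- accuracy_from_predictions(pooled$truth, pooled$.pred, lv)
  list(per_class = per_class,
       overall = 100 * mean(pooled$truth == as.character(pooled$.pred)),
       confusion = confusion_matrix_percent(pooled$truth, pooled$.pred, lv),
       predictions = pooled)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps thresholds over the unique scores of that class
#' (treating the class as positive), yielding a staircase from (0, 0) to
#' (1, 1); ties share a threshold, so constant scores give the chance
#' diagonal (AUC 0.5). AUC by the trapezoid rule.
#'
#' @param scores Matrix or tibble of per-class scores (columns named by
#'   class, or `.score_<class>` as produced by [predict_cells()]).
#' @param truth True labels; must contain at least two classes.
#' @return List: `curves` tibble (class, threshold, fpr, tpr) and `auc`
#'   named vector.
#' @export
roc_one_vs_rest <- function(scores, truth) {
  truth <- as.character(truth)
  if (length(unique(truth)) < 2) abort("ROC needs at least two classes in truth")
  if (is.data.frame(scores)) {
    sc <- as.matrix(scores[, grep("^\\.score_", names(scores)), drop = FALSE])
    colnames(sc) <- sub("^\\.score_", "", colnames(sc))
  } else sc <- as.matrix(scores)
  curves <- list(); auc <- numeric(0)
  for (cl in colnames(sc)) {
    pos <- truth == cl
    if (!any(pos) || all(pos)) next
    s <- sc[, cl]
    th <- sort(unique(s), decreasing = TRUE)
    tp <- vapply(th, function(t) sum(s >= t & pos), numeric(1))
    fp <- vapply(th, function(t) sum(s >= t & !pos), numeric(1))
    tpr <- c(0, tp / sum(pos), 1)
    fpr <- c(0, fp / sum(!pos), 1)
    a <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
    curves[[cl]] <- tibble(class = cl, threshold = c(Inf, th, -Inf),
                           fpr = fpr, tpr = tpr)
    auc[cl] <- a
  }
  list(curves = bind_rows(curves), auc = auc)
}

#' Learning curve: accuracy as a function of training-set size
#'
#' For each training fraction, draws a stratified training subsample,
#' evaluates on the held-out remainder and averages the overall accuracy
#' over repeats.
#'
#' @param spec A [classifier_spec()].
#' @param table Labelled feature table.
#' @param fractions Training fractions in (0, 1).
#' @param repeats Subsample repeats per fraction.
#' @param seed Integer seed.
#' @return Tibble: fraction, mean_accuracy, sd_accuracy.
#' @export
learning_curve <- function(spec, table, fractions = c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8),
                           repeats = 3, seed = 1) {
  if (any(fractions <= 0 | fractions >= 1)) abort("fractions must lie in (0, 1)")
  lv <- intersect(phenotype_levels(), unique(table$class))
  out <- list()
  for (fr in fractions) {
    accs <- numeric(repeats)
    for (r in seq_len(repeats)) {
      sp <- split_train_test(table, fr, seed = seed + 1000 * r + round(1e5 * fr))
      if (!nrow(sp$test)) abort("fraction leaves an empty test set")
      spec_r <- spec; spec_r$rng_seed <- spec$rng_seed + r
      model <- fit_classifier(spec_r, sp$train, probabilities = FALSE)
      p <- predict_cells(model, sp$test)
      accs[r] <- 100 * mean(sp$test$class == as.character(p$.pred))
    }
    out[[length(out) + 1]] <- tibble(fraction = fr,
                                     mean_accuracy = mean(accs),
                                     sd_accuracy = if (repeats > 1) sd(accs) else 0)
  }
  bind_rows(out)
}

#' Evaluate the five-classifier protocol on a labelled feature table
#'
#' Reproduces the evaluation protocol: stratified 50/50 train/test split with
#' held-out ROC curves, plus pooled stratified 10-fold cross-validation
#' accuracies on the full table (both are reported and labelled; per-class
#' accuracy is class recall, the diagonal of the row-percentage confusion
#' matrix).
#'
#' @param table Labelled feature table.
#' @param classifiers Named list of [classifier_spec()]s.
#' @param split_fraction Training share of the held-out split.
#' @param folds CV folds.
#' @param seed Integer seed.
#' @param learning_curves Also compute per-classifier learning curves
#'   (slower).
#' @param lc_fractions Fractions for the learning curves.
#' @return A `cyto_eval` object with elements `cv`, `holdout`, `roc`,
#'   `learning` (optional), `classes`, `n_cells` and `seed`.
#' @export
evaluate_classifiers <- function(table, classifiers = default_classifiers(),
                                 split_fraction = 0.5, folds = 10, seed = 1,
                                 learning_curves = FALSE,
                                 lc_fractions = c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8)) {
  lv <- intersect(phenotype_levels(), unique(table$class))
  sp <- split_train_test(table, split_fraction, seed = seed)
  cv <- list(); holdout <- list(); roc <- list(); learning <- list()
  for (nm in names(classifiers)) {
    spec <- classifiers[[nm]]
    spec$rng_seed <- seed
    cv[[nm]] <- cross_validate(spec, table, k = folds, seed = seed)
    model <- fit_classifier(spec, sp$train, probabilities = TRUE)
    p <- predict_cells(model, sp$test)
    holdout[[nm]] <- list(
      per_class = accuracy_from_predictions(sp$test$class, p$.pred, lv),
      overall = 100 * mean(sp$test$class == as.character(p$.pred)),
      confusion = confusion_matrix_percent(sp$test$class, p$.pred, lv))
    roc[[nm]] <- roc_one_vs_rest(p, sp$test$class)
    if (learning_curves) {
      learning[[nm]] <- learning_curve(spec, table, lc_fractions, seed = seed)
    }
  }
  structure(list(cv = cv, holdout = holdout, roc = roc,
                 learning = if (learning_curves) learning else NULL,
                 classes = lv, n_cells = nrow(table), seed = seed),
            class = "cyto_eval")
}

#' @export
print.cyto_eval <- function(x, ...) {
  cat("<cyto_eval> ", x$n_cells, " cells, ", length(x$classes),
      " classes, seed ", x$seed, "\n", sep = "")
  cat("10-fold CV per-class accuracy (%):\n")
  m <- vapply(x$cv, function(e) setNames(e$per_class$accuracy,
                                         e$per_class$class),
              numeric(length(x$classes)))
  print(round(t(m), 1))
  invisible(x)
}

#' Predict phenotypes for unlabelled ("blind") cells
#'
#' @param model A `cyto_model` from [fit_classifier()].
#' @param table Feature table without a required class column.
#' @return Tibble: provenance columns (if present) plus `.pred` and per-class
#'   score columns.
#' @export
predict_blind <- function(model, table) {
  p <- predict_cells(model, table)
  keep <- intersect(c("image_id", "object_id"), names(table))
  bind_cols(table[, keep, drop = FALSE], p)
}
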