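# broom-style tidiers for evaluation objects.

#' Tidy a `cyto_eval` object
#'
#' One row per classifier x class x protocol ("cv" = pooled 10-fold
#' cross-validation, "holdout" = held-out test half), with the per-class
#' accuracy (class recall, %).
#'
#' @param x A `cyto_eval` from [evaluate_classifiers()].
#' @param ... Unused.
#' @return A tibble: classifier, protocol, class, accuracy, n.
#' @export
tidy.cyto_eval <- function(x, ...) {
  rows <- list()
  for (nm in names(x$cv)) {
    rows[[length(rows) + 1]] <- mutate(x$cv[[nm]]$per_class,
                                       classifier = nm, protocol = "cv")
    rows[[length(rows) + 1]] <- mutate(x$holdout[[nm]]$per_class,
                                       classifier = nm, protocol = "holdout")
  }
  select(bind_rows(rows), "classifier", "protocol", "class", "accuracy", "n")
}

#' Summarise a `cyto_eval` object, one row per classifier
#'
#' @param x A `cyto_eval`.
#' @param ... Unused.
#' @return A tibble: classifier, cv_accuracy, holdout_accuracy, mean_auc.
#' @export
glance.cyto_eval <- function(x, ...) {
  bind_rows(lapply(names(x$cv), function(nm) {
    tibble(classifier = nm,
           cv_accuracy = x$cv[[nm]]$overall,
           holdout_accuracy = x$holdout[[nm]]$overall,
           mean_auc = mean(x$roc[[nm]]$auc))
  }))
}

#' Tidy a fitted `cyto_model`
#'
#' @param x A `cyto_model` from [fit_classifier()].
#' @param ... Unused.
#' @return A one-row tibble describing the fitted model.
#' @export
tidy.cyto_model <- function(x, ...) {
  tibble(method = x$spec$method, n_features = length(x$features),
         n_classes = length(x$levels), seed = x$spec$rng_seed)
}
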