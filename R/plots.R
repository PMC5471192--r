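# ggplot2 figures for evaluation results.

#' Confusion-matrix heatmap (row percentages)
#'
#' @param confusion Matrix from [confusion_matrix_percent()].
#' @return A ggplot object.
#' @export
plot_confusion_matrix <- function(confusion) {
  df <- as_tibble(as.table(confusion), .name_repair = ~ c("truth", "pred", "pct"))
  df$truth <- factor(df$truth, rev(rownames(confusion)))
  df$pred <- factor(df$pred, colnames(confusion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$pct)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 100), name = "%") +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' One-vs-rest ROC curves
#'
#' @param roc Result of [roc_one_vs_rest()].
#' @return A ggplot object; the dashed diagonal marks a random guess.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc$curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                           colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Learning curves per classifier
#'
#' @param learning Named list of [learning_curve()] tibbles (as stored on a
#'   `cyto_eval` fitted with `learning_curves = TRUE`).
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(learning) {
  df <- bind_rows(lapply(names(learning), function(nm) {
    mutate(learning[[nm]], classifier = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$mean_accuracy,
                                   colour = .data$classifier)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "training fraction", y = "accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Plot method for evaluation reports
#'
#' @param object A `cyto_eval`.
#' @param type `"accuracy"` (per-class CV accuracies), `"confusion"` (best
#'   classifier's CV confusion), `"roc"` or `"learning"`.
#' @param classifier Which classifier for `"confusion"`/`"roc"`; defaults to
#'   the highest CV accuracy.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_eval <- function(object, type = c("accuracy", "confusion",
                                                "roc", "learning"),
                               classifier = NULL, ...) {
  type <- match.arg(type)
  if (is.null(classifier)) {
    ov <- vapply(object$cv, `[[`, numeric(1), "overall")
    classifier <- names(ov)[which.max(ov)]
  }
  if (type == "accuracy") {
    df <- tidy.cyto_eval(object)
    df <- df[df$protocol == "cv", ]
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$class,
                                            y = .data$accuracy,
                                            fill = .data$classifier)) +
             ggplot2::geom_col(position = "dodge") +
             ggplot2::labs(y = "10-fold CV accuracy (%)") +
             ggplot2::theme_minimal())
  }
  if (type == "confusion") return(plot_confusion_matrix(object$cv[[classifier]]$confusion))
  if (type == "roc") return(plot_roc(object$roc[[classifier]]))
  if (is.null(object$learning)) abort("evaluation was run without learning curves")
  plot_learning_curve(object$learning)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
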