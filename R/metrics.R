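#' Confusion matrix of true vs predicted labels
#'
#' Rows are true classes, columns predicted classes. The percentage view is
#' row-normalised, so its diagonal equals per-class recall.
#'
#' @param truth,predicted Equal-length vectors of class labels.
#' @param classes Class universe (default 1..10).
#' @return A `cn_confusion` object: the count matrix with attributes
#'   `classes` and `percent` (row-normalised percentages).
#' @export
confusion <- function(truth, predicted, classes = 1:10) {
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length")
  }
  if (!all(truth %in% classes) || !all(predicted %in% classes)) {
    abort("labels outside the class universe")
  }
  t_f <- factor(truth, levels = classes)
  p_f <- factor(predicted, levels = classes)
  counts <- unclass(table(truth = t_f, predicted = p_f))
  pct <- 100 * counts / pmax(rowSums(counts), 1)
  structure(counts, classes = classes, percent = pct,
            class = c("cn_confusion", "matrix"))
}

cm_counts <- function(cm) {
  m <- unclass(cm)
  attributes(m) <- list(dim = dim(cm), dimnames = dimnames(cm))
  m
}

#' Per-class classification metrics
#'
#' One-vs-rest TP/FP/FN/TN per class: recall = TP/(TP+FN), precision =
#' TP/(TP+FP), specificity = TN/(TN+FP), balanced accuracy = (recall +
#' specificity)/2, F1 = harmonic mean of recall and precision. Rates with a
#' zero denominator are `NA` (undefined), not 0.
#'
#' @param cm A `cn_confusion` object.
#' @return A tibble with one row per class.
#' @export
per_class_metrics <- function(cm) {
  m <- cm_counts(cm)
  total <- sum(m)
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- total - tp - fn - fp
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  recall <- rate(tp, tp + fn)
  precision <- rate(tp, tp + fp)
  specificity <- rate(tn, tn + fp)
  f1 <- ifelse(!is.na(recall) & !is.na(precision) & (recall + precision) > 0,
               2 * recall * precision / (recall + precision), NA_real_)
  tibble(class = attr(cm, "classes"), support = as.integer(rowSums(m)),
         tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         tn = as.integer(tn), recall = unname(recall),
         precision = unname(precision), specificity = unname(specificity),
         balanced_accuracy = unname((recall + specificity) / 2),
         f1 = unname(f1))
}

#' Overall classification metrics
#'
#' Micro averages pool TP/FP/FN over classes (for single-label multiclass,
#' micro recall = micro precision = micro F1 = accuracy); macro averages are
#' unweighted means over classes with defined rates (the number excluded is
#' reported); weighted averages weight per-class rates by support.
#'
#' @param cm A `cn_confusion` object.
#' @return A one-row tibble of overall metrics, including the multiclass
#'   Matthews correlation coefficient.
#' @export
overall_metrics <- function(cm) {
  pc <- per_class_metrics(cm)
  m <- cm_counts(cm)
  total <- sum(m)
  tp <- sum(pc$tp); fp <- sum(pc$fp); fn <- sum(pc$fn)
  micro_recall <- tp / (tp + fn)
  micro_precision <- tp / (tp + fp)
  micro_f1 <- 2 * micro_recall * micro_precision /
    (micro_recall + micro_precision)
  macro <- function(x) mean(x, na.rm = TRUE)
  w <- pc$support / sum(pc$support)
  weighted <- function(x) sum(w * x, na.rm = TRUE) / sum(w[!is.na(x)])
  tibble(
    n = as.integer(total),
    accuracy = sum(diag(m)) / total,
    recall_micro = micro_recall,
    precision_micro = micro_precision,
    f1_micro = micro_f1,
    recall_macro = macro(pc$recall),
    precision_macro = macro(pc$precision),
    f1_macro = macro(pc$f1),
    recall_weighted = weighted(pc$recall),
    precision_weighted = weighted(pc$precision),
    f1_weighted = weighted(pc$f1),
    balanced_accuracy_macro = macro(pc$balanced_accuracy),
    mcc = multiclass_mcc(cm),
    n_classes_undefined = as.integer(sum(is.na(pc$precision) | is.na(pc$recall)))
  )
}

#' Multiclass Matthews correlation coefficient
#'
#' The K-class generalisation
#' \deqn{(c s - \sum_k p_k t_k) / \sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}}
#' with c = trace, s = total count, p_k = predicted (column) marginals and
#' t_k = true (row) marginals. A degenerate denominator (all mass in one row
#' or one column) returns 0 with a warning.
#'
#' @param cm A `cn_confusion` object or plain count matrix.
#' @return A number in [-1, 1].
#' @export
multiclass_mcc <- function(cm) {
  m <- cm_counts(cm)
  s <- sum(m)
  c_ <- sum(diag(m))
  p <- colSums(m)
  t_ <- rowSums(m)
  den2 <- (s^2 - sum(p^2)) * (s^2 - sum(t_^2))
  if (den2 <= 0) {
    warn("degenerate confusion matrix marginals: MCC set to 0")
    return(0)
  }
  (c_ * s - sum(p * t_)) / sqrt(den2)
}

#' Full evaluation of a prediction set
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Class universe (default 1..10).
#' @return A `cn_eval` list: `confusion`, `per_class`, `overall`. `tidy()`
#'   returns the per-class table, `glance()` the overall row.
#' @export
evaluate_predictions <- function(truth, predicted, classes = 1:10) {
  cm <- confusion(truth, predicted, classes = classes)
  structure(list(confusion = cm, per_class = per_class_metrics(cm),
                 overall = overall_metrics(cm)), class = "cn_eval")
}

#' @export
tidy.cn_eval <- function(x, ...) x$per_class

#' @export
glance.cn_eval <- function(x, ...) x$overall

#' @export
print.cn_eval <- function(x, ...) {
  cat("<cn_eval>\n  overall:\n")
  ov <- x$overall
  cat(sprintf("    micro recall %.3f | precision %.3f | MCC %.3f (n = %d)\n",
              ov$recall_micro, ov$precision_micro, ov$mcc, ov$n))
  invisible(x)
}

#' Heatmap of a confusion matrix
#'
#' Row-normalised percentage view; the diagonal equals per-class recall.
#'
#' @param object A `cn_confusion` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cn_confusion <- function(object, ...) {
  pct <- attr(object, "percent")
  df <- as_tibble(as.data.frame.table(pct, responseName = "percent"))
  names(df)[1:2] <- c("truth", "predicted")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$predicted,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$percent)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "True class", y = "Predicted class",
                  fill = "% of true") +
    ggplot2::theme_minimal()
}

#' Write / read an evaluation report
#'
#' TSV for the per-class table and confusion matrix (counts and percentage
#' views), JSON for the overall summary.
#'
#' @param eval A `cn_eval` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_metrics_report <- function(eval, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(eval$per_class, file.path(dir, "per_class_metrics.tsv"))
  jsonlite::write_json(as.list(eval$overall), file.path(dir, "overall_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  counts <- as_tibble(as.data.frame(cm_counts(eval$confusion)))
  readr::write_tsv(cbind(truth = rownames(cm_counts(eval$confusion)), counts),
                   file.path(dir, "confusion_counts.tsv"))
  pct <- as_tibble(as.data.frame(attr(eval$confusion, "percent")))
  readr::write_tsv(cbind(truth = rownames(attr(eval$confusion, "percent")), pct),
                   file.path(dir, "confusion_percent.tsv"))
  invisible(dir)
}
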