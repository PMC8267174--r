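# Evaluation: 2x2 confusion matrices with cancerous as the positive
# class, accuracy / per-class precision-recall-F1, ROC curves with
# trapezoid AUC, and the slide-accuracy percentage helper. Zero-denominator
# metrics are reported as NA, never coerced to 0.

#' Binary confusion matrix
#'
#' Counts follow the positive = cancerous convention: `tp` are cancerous
#' items called cancerous, `tn` normal items called normal.
#'
#' @param truth,predicted Equal-length binary vectors; 0/1, logical, or
#'   labels in `c("normal", "cancerous")` / `c("normal", "carcinoma")`.
#' @return A `confusion_matrix`: list with `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth (", length(truth), ") and predicted (", length(predicted),
         ") differ in length", call. = FALSE)
  }
  t01 <- to_binary(truth)
  p01 <- to_binary(predicted)
  structure(list(tp = sum(t01 == 1 & p01 == 1),
                 fp = sum(t01 == 0 & p01 == 1),
                 tn = sum(t01 == 0 & p01 == 0),
                 fn = sum(t01 == 1 & p01 == 0)),
            class = "confusion_matrix")
}

to_binary <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("labels must be binary (0/1)", call. = FALSE)
    return(as.integer(x))
  }
  y <- integer(length(x))
  y[x %in% c("cancerous", "carcinoma", "tumor", "positive")] <- 1L
  ok <- x %in% c("cancerous", "carcinoma", "tumor", "positive",
                 "normal", "negative")
  if (!all(ok)) stop("unrecognized labels: ",
                     paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
  y
}

#' Make a confusion matrix from the four counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts (positive = cancerous).
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("cancerous", "normal"),
                              predicted = c("cancerous", "normal")))
  print(m)
  invisible(x)
}

#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn)
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Per-class metrics use the standard formulas; for the normal class the
#' matrix roles are swapped (its "positives" are the normals). Metrics
#' with a zero denominator are `NA`.
#'
#' @param cm A `confusion_matrix`.
#' @return A `metrics_report`: overall `accuracy` plus a `per_class`
#'   tibble with precision, recall and F1 for normal and cancerous.
#' @examples
#' metrics_from_confusion(confusion_matrix(tp = 4830, fp = 334,
#'                                         tn = 4654, fn = 130))
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  stopifnot(total > 0)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  row_for <- function(class, tp, fp, fn) {
    precision <- safe_div(tp, tp + fp)
    recall <- safe_div(tp, tp + fn)
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    tibble::tibble(class = class, precision = precision, recall = recall,
                   f1 = f1)
  }
  per_class <- dplyr::bind_rows(
    row_for("normal", tp = cm$tn, fp = cm$fn, fn = cm$fp),
    row_for("cancerous", tp = cm$tp, fp = cm$fp, fn = cm$fn)
  )
  structure(list(accuracy = (cm$tp + cm$tn) / total,
                 per_class = per_class, confusion = cm, total = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("accuracy: ", sprintf("%.4f", x$accuracy), " (",
      sprintf("%.1f", 100 * x$accuracy), "%) on ", x$total, " items\n",
      sep = "")
  print(as.data.frame(x$per_class), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  pc <- x$per_class
  tibble::tibble(accuracy = x$accuracy,
                 precision_normal = pc$precision[pc$class == "normal"],
                 recall_normal = pc$recall[pc$class == "normal"],
                 f1_normal = pc$f1[pc$class == "normal"],
                 precision_cancerous = pc$precision[pc$class == "cancerous"],
                 recall_cancerous = pc$recall[pc$class == "cancerous"],
                 f1_cancerous = pc$f1[pc$class == "cancerous"],
                 total = x$total)
}

#' ROC curve and trapezoid AUC
#'
#' Sweeps the decision threshold over the unique scores; the AUC is the
#' trapezoid area under the resulting curve, which equals the
#' Mann-Whitney U statistic with half credit for ties.
#'
#' @param scores Numeric scores in `[0, 1]` (larger = more cancerous).
#' @param truth Binary labels as in [confusion()]; both classes required.
#' @return A `roc_curve`: `points` tibble (threshold, fpr, tpr) and `auc`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc
#' @export
roc_auc <- function(scores, truth) {
  y <- to_binary(truth)
  stopifnot(length(scores) == length(y), all(scores >= 0 & scores <= 1))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes; got ", n_pos, " positive and ",
         n_neg, " negative", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(th) {
    c(fpr = sum(scores >= th & y == 0) / n_neg,
      tpr = sum(scores >= th & y == 1) / n_pos)
  }, numeric(2)))
  points <- tibble::tibble(threshold = thr, fpr = pts[, "fpr"],
                           tpr = pts[, "tpr"])
  auc <- sum(diff(points$fpr) *
               (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC = ", sprintf("%.4f", x$auc), " (", x$n_pos,
      " positive / ", x$n_neg, " negative)\n", sep = "")
  invisible(x)
}

#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.4f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Slide-level accuracy percentage
#'
#' @param n_total Number of slides evaluated (> 0).
#' @param n_misclassified Number of slides misclassified.
#' @return Percentage `100 * (n_total - n_misclassified) / n_total`.
#' @examples
#' slide_accuracy(52, 5)
#' @export
slide_accuracy <- function(n_total, n_misclassified) {
  if (n_total <= 0 || n_misclassified < 0 || n_misclassified > n_total) {
    stop("need 0 <= n_misclassified <= n_total and n_total > 0",
         call. = FALSE)
  }
  100 * (n_total - n_misclassified) / n_total
}
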