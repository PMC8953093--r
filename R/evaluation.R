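# Node-level evaluation of delineation output: confusion matrices,
# one-vs-rest class metrics, macro averages, precision-recall curves.

#' Confusion matrix of per-sample class labels
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param y_true,y_pred Integer class vectors of equal length with
#'   values `< n_classes`.
#' @param n_classes Number of classes.
#' @param class_names Optional class names (defaults to the waveform
#'   names when `n_classes == 5`).
#' @param waveforms_only Drop nodes whose true or predicted class is
#'   PAD (class 4) before counting, so metrics describe waveforms only.
#' @return An object of class `confusion_matrix` wrapping the
#'   `n_classes x n_classes` count matrix.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 5L,
                             class_names = NULL, waveforms_only = FALSE) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop(sprintf("confusion_matrix: length mismatch (%d vs %d)",
                 length(y_true), length(y_pred)), call. = FALSE)
  if (anyNA(y_true) || anyNA(y_pred) ||
      any(y_true < 0L | y_true >= n_classes) ||
      any(y_pred < 0L | y_pred >= n_classes))
    stop("confusion_matrix: class values must lie in [0, n_classes)",
         call. = FALSE)
  if (is.null(class_names))
    class_names <- if (n_classes == 5L) WAVE_CLASS_NAMES else
      as.character(seq_len(n_classes) - 1L)
  if (waveforms_only) {
    keep <- y_true != WAVE_CLASSES[["PAD"]] & y_pred != WAVE_CLASSES[["PAD"]]
    y_true <- y_true[keep]
    y_pred <- y_pred[keep]
  }
  counts <- matrix(0L, n_classes, n_classes,
                   dimnames = list(true = class_names,
                                   predicted = class_names))
  tab <- table(factor(y_true, levels = 0:(n_classes - 1L)),
               factor(y_pred, levels = 0:(n_classes - 1L)))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, class_names = class_names),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows = true, cols = predicted)\n")
  print(x$counts)
  invisible(x)
}

#' One-vs-rest metrics for one class of a confusion matrix
#'
#' Sensitivity TP/(TP+FN), precision TP/(TP+FP), specificity
#' TN/(TN+FP), accuracy (TP+TN)/total, and the F1 harmonic mean.
#' Ratios with zero denominators are reported as `NA` (flagged in
#' `$undefined`), never silently as 0.
#'
#' @param cm A [confusion_matrix()].
#' @param k 0-based class index.
#' @return An object of class `class_metrics`: list with `sensitivity`,
#'   `precision`, `specificity`, `accuracy`, `f1`, the raw `counts`,
#'   and `undefined` (character vector of metrics with 0/0).
#' @export
class_metrics <- function(cm, k) {
  stopifnot(inherits(cm, "confusion_matrix"))
  K <- nrow(cm$counts)
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k >= K)
    stop(sprintf("class_metrics: class index %s outside [0, %d)",
                 format(k), K), call. = FALSE)
  i <- as.integer(k) + 1L
  m <- cm$counts
  tp <- m[i, i]
  fn <- sum(m[i, ]) - tp
  fp <- sum(m[, i]) - tp
  tn <- sum(m) - tp - fn - fp
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  prec <- ratio(tp, tp + fp)
  spec <- ratio(tn, tn + fp)
  acc <- ratio(tp + tn, sum(m))
  f1 <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  vals <- c(sensitivity = sens, precision = prec, specificity = spec,
            accuracy = acc, f1 = f1)
  structure(list(sensitivity = sens, precision = prec,
                 specificity = spec, accuracy = acc, f1 = f1,
                 counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 undefined = names(vals)[is.na(vals)],
                 class_name = cm$class_names[[i]]),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf(
    "<class_metrics %s> sens %.4f prec %.4f spec %.4f acc %.4f f1 %.4f\n",
    x$class_name, x$sensitivity, x$precision, x$specificity, x$accuracy,
    x$f1))
  if (length(x$undefined))
    cat("  undefined (0/0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Macro-averaged metrics over a set of classes
#'
#' Arithmetic mean of the per-class one-vs-rest metrics (the usual
#' summary convention for delineation tables); micro aggregation (pool
#' the one-vs-rest counts first) is available by flag.
#'
#' @param cm A [confusion_matrix()].
#' @param classes 0-based class indices to average over.
#' @param average `"macro"` or `"micro"`.
#' @return Named numeric vector `sensitivity`, `precision`,
#'   `specificity`, `accuracy`, `f1`.
#' @export
macro_metrics <- function(cm, classes = 0:2, average = c("macro", "micro")) {
  average <- match.arg(average)
  if (average == "macro") {
    per <- lapply(classes, function(k) class_metrics(cm, k))
    vapply(c("sensitivity", "precision", "specificity", "accuracy", "f1"),
           function(nm) mean(vapply(per, `[[`, 0, nm)), 0)
  } else {
    cnt <- rowSums(vapply(classes,
                          function(k) class_metrics(cm, k)$counts,
                          numeric(4)))
    tp <- cnt[["tp"]]; fp <- cnt[["fp"]]; fn <- cnt[["fn"]]; tn <- cnt[["tn"]]
    sens <- tp / (tp + fn); prec <- tp / (tp + fp)
    c(sensitivity = sens, precision = prec,
      specificity = tn / (tn + fp),
      accuracy = (tp + tn) / (tp + fp + fn + tn),
      f1 = 2 * prec * sens / (prec + sens))
  }
}

#' Precision-recall curve and area under it
#'
#' Sweeps every distinct score as a threshold (descending), yielding
#' one precision/recall point per threshold; recall is nondecreasing
#' along the sweep.  The area is the trapezoid over recall, anchored at
#' recall 0 with the first point's precision.
#'
#' @param scores Predicted probabilities of the positive class, in
#'   `[0, 1]`.
#' @param y_true 0/1 indicator of the positive class (both classes must
#'   occur).
#' @return List with `points` (data frame `threshold`, `recall`,
#'   `precision`) and `auc`.
#' @export
pr_curve <- function(scores, y_true) {
  y_true <- as.integer(y_true)
  if (length(scores) != length(y_true))
    stop("pr_curve: length mismatch", call. = FALSE)
  if (any(scores < 0 | scores > 1))
    stop("pr_curve: scores must lie in [0, 1]", call. = FALSE)
  npos <- sum(y_true == 1L)
  if (npos == 0L || npos == length(y_true))
    stop("pr_curve: both classes must be present in y_true", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]
  ss <- scores[ord]
  tp_cum <- cumsum(ys)
  n_cum <- seq_along(ys)
  last <- which(!duplicated(ss, fromLast = TRUE))  # last index per score
  thr <- ss[last]
  recall <- tp_cum[last] / npos
  precision <- tp_cum[last] / n_cum[last]
  auc <- sum(diff(c(0, recall)) *
               (precision + c(precision[[1L]], head(precision, -1L))) / 2)
  list(points = data.frame(threshold = thr, recall = recall,
                           precision = precision),
       auc = auc)
}
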