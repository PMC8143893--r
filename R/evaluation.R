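#' Confusion matrix
#'
#' `counts[i, j]` = number of samples with actual class `i` predicted as
#' class `j` (rows = actual, columns = predicted).
#'
#' @param actual,predicted label vectors of equal length.
#' @param classes class names fixing row/column order; defaults to the
#'   sorted union of observed labels. Unknown labels are an error.
#' @return Integer `K x K` matrix with dimnames
#'   `list(actual = classes, predicted = classes)`.
#' @examples
#' confusionCounts(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
#' @export
confusionCounts <- function(actual, predicted, classes = NULL) {
  actual <- as.character(actual); predicted <- as.character(predicted)
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(actual, predicted)))
  bad <- setdiff(unique(c(actual, predicted)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  K <- length(classes)
  cm <- matrix(0L, K, K, dimnames = list(actual = classes,
                                         predicted = classes))
  for (i in seq_along(actual))
    cm[actual[i], predicted[i]] <- cm[actual[i], predicted[i]] + 1L
  cm
}

#' One-vs-rest counts for one class
#'
#' `TP = cm[k, k]`, `FN` = rest of row k, `FP` = rest of column k,
#' `TN` = everything else.
#'
#' @param cm confusion matrix from [confusionCounts()].
#' @param k class index or name.
#' @return Named numeric vector `(TP, TN, FP, FN)`.
#' @export
oneVsRestCounts <- function(cm, k) {
  TP <- cm[k, k]
  FN <- sum(cm[k, ]) - TP
  FP <- sum(cm[, k]) - TP
  TN <- sum(cm) - TP - FP - FN
  c(TP = TP, TN = TN, FP = FP, FN = FN)
}

#' Classification metrics from one-vs-rest counts (percent)
#'
#' accuracy = (TP+TN)/(TP+TN+FP+FN), specificity = TN/(TN+FP),
#' sensitivity = recall = TP/(TP+FN), precision = TP/(TP+FP),
#' F1 = 2*precision*recall/(precision+recall), each scaled to percent.
#' Zero-denominator cases return 0 and set the `degenerate` flag.
#'
#' @param TP,TN,FP,FN nonnegative counts; their total must be positive.
#' @return Named list: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `recall`, `f1` (percent) and logical `degenerate`.
#' @examples
#' metricsFromCounts(50, 40, 5, 5)$accuracy
#' @export
metricsFromCounts <- function(TP, TN, FP, FN) {
  total <- TP + TN + FP + FN
  if (total <= 0) stop("total count must be > 0", call. = FALSE)
  if (any(c(TP, TN, FP, FN) < 0))
    stop("counts must be >= 0", call. = FALSE)
  degenerate <- FALSE
  safe <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  sens <- safe(TP, TP + FN)
  spec <- safe(TN, TN + FP)
  prec <- safe(TP, TP + FP)
  f1 <- if (prec + sens == 0) { degenerate <- TRUE; 0 } else
    2 * prec * sens / (prec + sens)
  list(accuracy = 100 * (TP + TN) / total,
       sensitivity = 100 * sens, specificity = 100 * spec,
       precision = 100 * prec, recall = 100 * sens, f1 = 100 * f1,
       degenerate = degenerate)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique scores as thresholds (equal scores grouped into one
#' step), records the true/false positive rates, and integrates the AUC by
#' the trapezoidal rule.
#'
#' @param scores per-sample positive-class scores or probabilities.
#' @param actual binary labels (0/1, logical, or two-level factor where the
#'   second sorted level is positive).
#' @return List of class `"ROCCurve"`: `thresholds`, `fpr`, `tpr`, `auc`.
#' @examples
#' rocCurve(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc
#' @export
rocCurve <- function(scores, actual) {
  if (is.factor(actual) || is.character(actual)) {
    lv <- sort(unique(as.character(actual)))
    if (length(lv) != 2L)
      stop("actual must be binary; got levels ", paste(lv, collapse = ", "),
           call. = FALSE)
    actual <- as.numeric(as.character(actual) == lv[2])
  }
  actual <- as.numeric(actual != 0)
  nPos <- sum(actual == 1); nNeg <- sum(actual == 0)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & actual == 1),
                     numeric(1)) / nPos)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & actual == 0),
                     numeric(1)) / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, thr), fpr = fpr, tpr = tpr, auc = auc),
            class = "ROCCurve")
}

#' Full evaluation report
#'
#' Confusion matrix, per-class one-vs-rest metric suite, macro averages
#' (unweighted means over classes), overall accuracy, and one-vs-rest ROC
#' curves with AUC when class probabilities are supplied.
#'
#' @param actual,predicted label vectors.
#' @param proba optional matrix (samples x classes) of class probabilities
#'   with column names matching `classes`.
#' @param classes class-name vector fixing order.
#' @return List of class `"EvaluationReport"`: `confusion`, `perClass`
#'   (data.frame), `macro` (list), `overallAccuracy` (percent), `roc`
#'   (named list of [rocCurve()] results, or `NULL`).
#' @export
evaluationReport <- function(actual, predicted, proba = NULL,
                             classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(actual)))
  cm <- confusionCounts(actual, predicted, classes)
  per <- lapply(classes, function(cl) {
    cnt <- oneVsRestCounts(cm, cl)
    m <- metricsFromCounts(cnt["TP"], cnt["TN"], cnt["FP"], cnt["FN"])
    data.frame(class = cl, TP = cnt["TP"], TN = cnt["TN"], FP = cnt["FP"],
               FN = cnt["FN"], accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               precision = m$precision, f1 = m$f1,
               degenerate = m$degenerate, row.names = NULL)
  })
  per <- do.call(rbind, per)
  macro <- list(accuracy = mean(per$accuracy),
                sensitivity = mean(per$sensitivity),
                specificity = mean(per$specificity),
                precision = mean(per$precision), f1 = mean(per$f1))
  roc <- NULL
  if (!is.null(proba)) {
    roc <- lapply(classes, function(cl) {
      rocCurve(proba[, cl], as.numeric(as.character(actual) == cl))
    })
    names(roc) <- classes
  }
  structure(list(confusion = cm, perClass = per, macro = macro,
                 overallAccuracy = 100 * sum(diag(cm)) / sum(cm),
                 roc = roc),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("EvaluationReport\n\nConfusion matrix (rows = actual):\n")
  print(x$confusion)
  cat(sprintf("\nOverall accuracy: %.2f%%\n", x$overallAccuracy))
  cat(sprintf("Macro: sens %.2f%% | spec %.2f%% | prec %.2f%% | F1 %.2f%%\n",
              x$macro$sensitivity, x$macro$specificity, x$macro$precision,
              x$macro$f1))
  if (!is.null(x$roc)) {
    aucs <- vapply(x$roc, function(r) r$auc, numeric(1))
    cat("One-vs-rest AUC:",
        paste(sprintf("%s %.3f", names(aucs), aucs), collapse = " | "), "\n")
  }
  invisible(x)
}
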