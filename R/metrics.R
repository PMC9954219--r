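# Confusion matrix, weighted one-vs-rest metrics, the misclassification
# audit, and one-vs-rest ROC/AUC with micro/macro averaging.

#' Confusion matrix over the six classes
#'
#' Rows are true classes, columns predicted, both in the fixed label order.
#'
#' @param true,pred Equal-length label vectors (factor/character).
#' @param labels Class label order; default [class_labels()].
#' @return 6x6 integer matrix of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(true, pred, labels = class_labels()) {
  true <- as.character(true); pred <- as.character(pred)
  if (length(true) != length(pred))
    stop("true and predicted label sequences differ in length")
  bad <- setdiff(unique(c(true, pred)), labels)
  if (length(bad))
    stop(sprintf("invalid label(s): %s", paste(bad, collapse = ", ")))
  cm <- table(factor(true, levels = labels), factor(pred, levels = labels))
  structure(unclass(as.matrix(cm)), dimnames = list(true = labels,
                                                    predicted = labels),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = true, columns = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class and weighted classification metrics
#'
#' For each class c, one-vs-rest counts are TP = \code{cm[c, c]}, FN = row sum minus
#' TP, FP = column sum minus TP, TN = the remainder; from these, accuracy
#' A = (TP+TN)/(TP+FN+FP+TN), recall R = TP/(TP+FN), specificity
#' S = TN/(FP+TN), precision P = TP/(TP+FP) and F1 = 2TP/(2TP+FN+FP).
#' Weighted values are support-weighted means over classes; overall accuracy
#' is trace/total. Classes with zero support are reported as NA and excluded
#' from the weighting, with a warning.
#'
#' @param cm A [confusion_matrix()] (any square labeled matrix works).
#' @return Object of class \code{metrics_report}: \code{per_class} data
#'   frame, \code{weighted} named vector, \code{overall_accuracy},
#'   \code{support}.
#' @export
class_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  labels <- rownames(cm)
  support <- rowSums(cm)
  per <- data.frame(class = labels, support = support,
                    accuracy = NA_real_, precision = NA_real_,
                    recall = NA_real_, specificity = NA_real_,
                    f1 = NA_real_, row.names = NULL)
  for (i in seq_along(labels)) {
    tp <- cm[i, i]; fn <- support[i] - tp
    fp <- sum(cm[, i]) - tp; tn <- total - tp - fn - fp
    if (support[i] == 0) next
    per$accuracy[i] <- (tp + tn) / total
    per$recall[i] <- tp / (tp + fn)
    per$specificity[i] <- tn / (fp + tn)
    per$precision[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    per$f1[i] <- 2 * tp / (2 * tp + fn + fp)
  }
  if (any(support == 0))
    warning(sprintf("class(es) with zero support excluded from weighting: %s",
                    paste(labels[support == 0], collapse = ", ")))
  ok <- support > 0
  w <- support[ok] / sum(support[ok])
  weighted <- vapply(c("accuracy", "precision", "recall", "specificity", "f1"),
                     function(m) sum(w * per[[m]][ok]), 0)
  structure(list(per_class = per, weighted = weighted,
                 overall_accuracy = sum(diag(cm)) / total,
                 support = support),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("overall accuracy: %.2f%%\n", 100 * x$overall_accuracy))
  cat("weighted metrics (%):\n")
  print(round(100 * x$weighted, 2))
  cat("per class:\n")
  out <- x$per_class
  out[, 3:7] <- round(100 * out[, 3:7], 2)
  print(out, row.names = FALSE)
  invisible(x)
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Misclassification audit from printed per-class recalls
#'
#' Per class, correct = round(recall/100 * support) (half-up) and errors =
#' support - correct; returns the summed error count. On the published
#' per-class recalls (100, 97.67, 97.20, 96.00, 96.50, 96.84) with supports
#' (300, 215, 215, 200, 200, 190) this yields 32.
#'
#' @param recalls_pct Per-class recalls in percent, in class-label order.
#' @param supports Per-class test supports.
#' @return Integer total error count, with per-class errors and the error
#'   rate on the summed support as attributes.
#' @export
misclassification_audit <- function(recalls_pct, supports) {
  if (any(recalls_pct < 0 | recalls_pct > 100))
    stop("recalls must be percentages in [0, 100]")
  correct <- round_half_up(recalls_pct / 100 * supports)
  errors <- supports - correct
  total <- as.integer(sum(errors))
  structure(total, per_class = as.integer(errors),
            support_total = as.integer(sum(supports)),
            error_rate = total / sum(supports))
}

binary_roc <- function(scores, truth) {
  # threshold sweep: points ordered by decreasing score; AUC by trapezoid
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- truth[o]
  P <- sum(truth); N <- length(truth) - P
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(s[-1] != s[-length(s)], TRUE) # last point of each tie group
  tpr <- c(0, tp[keep] / max(P, 1))
  fpr <- c(0, fp[keep] / max(N, 1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' One-vs-rest ROC curves and a single AUC
#'
#' Builds a one-vs-rest ROC per class by threshold sweep; the single
#' reported AUC is the micro-average (a binary ROC over the flattened
#' class-membership problem) by default, or the macro-average (mean of
#' per-class AUCs) with \code{average = "macro"}. Classes absent from the
#' truth vector are flagged and excluded.
#'
#' @param scores N x K probability matrix (columns in class-label order).
#' @param true Label vector of length N.
#' @param labels Class label order.
#' @param average "micro" or "macro".
#' @return Object of class \code{roc_report}: per-class curves and AUCs,
#'   plus the single averaged \code{auc}.
#' @export
roc_auc <- function(scores, true, labels = class_labels(),
                    average = c("micro", "macro")) {
  average <- match.arg(average)
  scores <- as.matrix(scores)
  true <- as.character(true)
  per_class <- vector("list", length(labels))
  names(per_class) <- labels
  missing_cls <- character(0)
  for (i in seq_along(labels)) {
    truth <- true == labels[i]
    if (!any(truth)) { missing_cls <- c(missing_cls, labels[i]); next }
    per_class[[i]] <- binary_roc(scores[, i], truth)
  }
  if (length(missing_cls))
    warning(sprintf("class(es) absent from truth, curve undefined: %s",
                    paste(missing_cls, collapse = ", ")))
  present <- !vapply(per_class, is.null, logical(1))
  auc <- if (average == "micro") {
    truth_flat <- as.vector(vapply(labels[present], function(l) true == l,
                                   logical(length(true))))
    binary_roc(as.vector(scores[, present]), truth_flat)$auc
  } else {
    mean(vapply(per_class[present], function(z) z$auc, 0))
  }
  structure(list(per_class = per_class, auc = auc, average = average),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("%s-averaged AUC: %.4f\n", x$average, x$auc))
  for (nm in names(x$per_class))
    if (!is.null(x$per_class[[nm]]))
      cat(sprintf("  %-4s AUC %.4f\n", nm, x$per_class[[nm]]$auc))
  invisible(x)
}
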