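#' Confusion matrix from true and predicted labels
#'
#' @param labels_true,labels_pred Integer labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return `n_classes x n_classes` integer matrix; rows are true classes,
#'   columns predicted.
#' @export
confusion <- function(labels_true, labels_pred, n_classes) {
  stop_if_not(length(labels_true) == length(labels_pred),
              "label vectors must have equal length")
  ok <- function(l) all(l >= 1 & l <= n_classes & l == round(l))
  if (length(labels_true) > 0) {
    stop_if_not(ok(labels_true) && ok(labels_pred),
                sprintf("labels must be integers in 1..%d", n_classes))
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(labels_true)) {
    cm[labels_true[i], labels_pred[i]] <- cm[labels_true[i], labels_pred[i]] + 1L
  }
  cm
}

#' Balanced accuracy: mean per-class recall
#'
#' @param cm Confusion matrix (rows = true, columns = predicted).
#' @return Scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(cm) {
  support <- rowSums(cm)
  if (any(support == 0)) {
    stop("true class(es) with no samples: ",
         paste(which(support == 0), collapse = ", "), call. = FALSE)
  }
  mean(diag(cm) / support)
}

#' Area under the ROC curve (binary)
#'
#' Mann-Whitney / midrank formulation: the probability that a random positive
#' is scored above a random negative, ties counted one half. Equals the
#' trapezoidal area under the ROC curve.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels (0/1, logical, or two-level factor/values).
#' @return Scalar in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stop_if_not(length(scores) == length(labels), "scores and labels must align")
  lv <- sort(unique(labels))
  stop_if_not(length(lv) == 2, "labels must contain exactly two classes")
  pos <- labels == lv[2]
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Support-weighted F1 score
#'
#' Per-class F1 (harmonic mean of precision and recall), weighted by the
#' class support; a class whose precision + recall is 0 contributes F1 = 0
#' (with a warning).
#'
#' @param cm Confusion matrix (rows = true, columns = predicted).
#' @return Scalar in `[0, 1]`.
#' @export
weighted_f1 <- function(cm) {
  n <- sum(cm)
  stop_if_not(n > 0, "empty confusion matrix")
  support <- rowSums(cm)
  f1 <- vapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    prec <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec <- if (support[i] > 0) tp / support[i] else 0
    if (prec + rec == 0) {
      warning(sprintf("class %d has precision + recall = 0; F1 set to 0", i),
              call. = FALSE)
      0
    } else {
      2 * prec * rec / (prec + rec)
    }
  }, numeric(1))
  sum(support * f1) / n
}

#' Cohen's kappa: chance-corrected agreement
#'
#' @param cm Confusion matrix (rows = true, columns = predicted).
#' @return Scalar in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  n <- sum(cm)
  stop_if_not(n > 0, "empty confusion matrix")
  p_o <- sum(diag(cm)) / n
  p_e <- sum((rowSums(cm) / n) * (colSums(cm) / n))
  if (abs(1 - p_e) < .Machine$double.eps * 4) {
    stop("degenerate table: expected agreement is 1, kappa undefined",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Assemble the standard evaluation report
#'
#' Balanced accuracy, weighted F1, Cohen's kappa, per-class precision/recall,
#' and — for binary problems with scores supplied — AUROC.
#'
#' @param labels_true,labels_pred Integer labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @param scores Optional positive-class scores (binary problems only).
#' @return A `metrics_report` list.
#' @export
metrics_report <- function(labels_true, labels_pred, n_classes, scores = NULL) {
  cm <- confusion(labels_true, labels_pred, n_classes)
  support <- rowSums(cm)
  prec <- vapply(seq_len(n_classes), function(i) {
    if (sum(cm[, i]) > 0) cm[i, i] / sum(cm[, i]) else NA_real_
  }, numeric(1))
  rec <- ifelse(support > 0, diag(cm) / support, NA_real_)
  rep <- list(
    bac = balanced_accuracy(cm),
    auroc = if (!is.null(scores) && n_classes == 2) auroc(scores, labels_true) else NA_real_,
    weighted_f1 = weighted_f1(cm),
    kappa = cohens_kappa(cm),
    precision = prec,
    recall = rec,
    confusion = cm
  )
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("BAC          %.4f\n", x$bac))
  cat(sprintf("AUROC        %s\n",
              if (is.na(x$auroc)) "(binary only)" else sprintf("%.4f", x$auroc)))
  cat(sprintf("weighted F1  %.4f\n", x$weighted_f1))
  cat(sprintf("kappa        %.4f\n", x$kappa))
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param rep A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(rep, path) {
  out <- list(bac = rep$bac, auroc = rep$auroc, weighted_f1 = rep$weighted_f1,
              kappa = rep$kappa, precision = rep$precision, recall = rep$recall,
              confusion = rep$confusion)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
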