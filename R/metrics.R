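#' Multiclass confusion counts
#'
#' Tabulates true vs predicted labels over a fixed class order. Entry
#' (i, j) counts samples of true class i predicted as class j; per-class
#' true positives, false positives and false negatives are derived from
#' the matrix.
#'
#' @param true_labels,predicted_labels equal-length label vectors, all
#'   values contained in `class_order`.
#' @param class_order character vector fixing the class set and ordering.
#' @return object of class `confusion_counts`: list with `matrix` (L x L),
#'   `tp`, `fp`, `fn` (named integer vectors), `n` and `class_order`.
#' @export
confusion <- function(true_labels, predicted_labels, class_order) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stopf("length mismatch: %d true vs %d predicted labels",
          length(true_labels), length(predicted_labels))
  }
  if (length(true_labels) == 0L) stopf("empty label vectors")
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), class_order)
  if (length(unknown)) {
    stopf("labels not in class_order: %s", paste(unknown, collapse = ", "))
  }
  tf <- factor(true_labels, levels = class_order)
  pf <- factor(predicted_labels, levels = class_order)
  m <- unclass(table(tf, pf))
  dimnames(m) <- list(true = class_order, predicted = class_order)
  tp <- diag(m)
  structure(
    list(matrix = m, tp = tp, fp = colSums(m) - tp, fn = rowSums(m) - tp,
         n = length(true_labels), class_order = class_order),
    class = "confusion_counts"
  )
}

#' Summarize a confusion matrix into classification metrics
#'
#' Computes per-class precision, recall and F1 (harmonic mean), overall
#' accuracy (trace / n), macro F1 (unweighted mean of per-class F1) and
#' weighted F1 (per-class F1 weighted by the true class proportions
#' `w_i = n_i / n`). Undefined 0/0 ratios are set to 0, so classes absent
#' from both truth and prediction contribute F1 = 0 with weight 0.
#'
#' @param cc a [confusion()] object.
#' @param per_fold_acc optional numeric vector of per-fold accuracies to
#'   carry along (filled by the cross-validation engine).
#' @param mcc optional multiclass MCC to attach (see [mcc_multiclass()]).
#' @return object of class `evaluation_summary`: list with `acc`, `mcc`
#'   (may be NA if not supplied), `macro_f1`, `weighted_f1`, `per_class`
#'   (data.frame class/precision/recall/f1/weight), `per_fold_acc`, `n`.
#' @export
summarize_confusion <- function(cc, per_fold_acc = NULL, mcc = NA_real_) {
  stopifnot(inherits(cc, "confusion_counts"))
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe_div(cc$tp, cc$tp + cc$fp)
  recall <- safe_div(cc$tp, cc$tp + cc$fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  w <- (cc$tp + cc$fn) / cc$n
  structure(
    list(acc = sum(cc$tp) / cc$n,
         mcc = mcc,
         macro_f1 = mean(f1),
         weighted_f1 = sum(w * f1),
         per_class = data.frame(class = cc$class_order,
                                precision = as.numeric(precision),
                                recall = as.numeric(recall),
                                f1 = as.numeric(f1),
                                weight = as.numeric(w),
                                row.names = NULL),
         per_fold_acc = per_fold_acc,
         n = cc$n),
    class = "evaluation_summary"
  )
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("evaluation_summary (n = %d): ACC %.4f, MCC %s, macro F1 %.4f, weighted F1 %.4f\n",
              x$n, x$acc, ifelse(is.na(x$mcc), "NA", sprintf("%.4f", x$mcc)),
              x$macro_f1, x$weighted_f1))
  invisible(x)
}

#' Multiclass Matthews correlation coefficient
#'
#' Builds n x L one-hot indicator matrices X (truth) and Y (prediction)
#' and returns `cov(X, Y) / sqrt(cov(X, X) * cov(Y, Y))`, where
#' `cov(A, B)` is the sum over classes and samples of the products of
#' column-centered entries (any common normalization constant cancels in
#' the ratio). For two classes this reduces to the classical binary MCC.
#' Returns 0 when the denominator vanishes (constant truth or constant
#' prediction).
#'
#' @inheritParams confusion
#' @return a single number in \[-1, 1\].
#' @export
mcc_multiclass <- function(true_labels, predicted_labels, class_order) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stopf("length mismatch: %d true vs %d predicted labels",
          length(true_labels), length(predicted_labels))
  }
  if (length(true_labels) == 0L) stopf("empty label vectors")
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), class_order)
  if (length(unknown)) {
    stopf("labels not in class_order: %s", paste(unknown, collapse = ", "))
  }
  n <- length(true_labels)
  L <- length(class_order)
  one_hot <- function(labels) {
    m <- matrix(0, nrow = n, ncol = L, dimnames = list(NULL, class_order))
    m[cbind(seq_len(n), match(labels, class_order))] <- 1
    m
  }
  X <- scale(one_hot(true_labels), center = TRUE, scale = FALSE)
  Y <- scale(one_hot(predicted_labels), center = TRUE, scale = FALSE)
  cov_xy <- sum(X * Y)
  cov_xx <- sum(X * X)
  cov_yy <- sum(Y * Y)
  if (cov_xx == 0 || cov_yy == 0) return(0)
  cov_xy / sqrt(cov_xx * cov_yy)
}
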