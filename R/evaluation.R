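#' Confusion counts for binary tumor classification
#'
#' Tallies the standard 2x2 table with the tumor class (1) as positive:
#' true positives are tumor images detected as abnormal, true negatives
#' normal images reported normal, false positives tumor-free images flagged
#' as tumorous, false negatives tumor images missed.
#'
#' @param labels_true,labels_pred Equal-length 0/1 vectors.
#' @return A `confusion_counts` list with `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (!all(labels_true %in% c(0, 1)) || !all(labels_pred %in% c(0, 1))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  structure(
    list(
      tp = sum(labels_true == 1 & labels_pred == 1),
      tn = sum(labels_true == 0 & labels_pred == 0),
      fp = sum(labels_true == 0 & labels_pred == 1),
      fn = sum(labels_true == 1 & labels_pred == 0)
    ),
    class = "confusion_counts"
  )
}

#' Diagnostic metrics on the percent scale
#'
#' \deqn{sensitivity = 100 \cdot TP / (TP + FN)}
#' \deqn{specificity = 100 \cdot TN / (TN + FP)}
#' \deqn{accuracy = 100 \cdot (TP + TN) / (TP + TN + FP + FN)}
#' \deqn{precision = 100 \cdot TP / (TP + FP)}
#' A ratio with a zero denominator is undefined and reported as `NA`
#' (never coerced to 0 or 100), with the matching `*_defined` flag set to
#' `FALSE`.
#'
#' @param counts A [confusion()] result, or a list with `tp`, `tn`, `fp`,
#'   `fn`.
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`,
#'   `precision` (percent or `NA`), the four `*_defined` flags, and the
#'   counts.
#' @examples
#' classification_metrics(confusion(rep(c(1, 0), c(9, 9)), rep(c(1, 0), c(9, 9))))
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  total <- tp + tn + fp + fn
  tibble::tibble(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    accuracy = ratio(tp + tn, total),
    precision = ratio(tp, tp + fp),
    sensitivity_defined = tp + fn > 0,
    specificity_defined = tn + fp > 0,
    accuracy_defined = total > 0,
    precision_defined = tp + fp > 0,
    tp = tp, tn = tn, fp = fp, fn = fn
  )
}

#' Dice overlap between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; 1 for identical non-empty masks. Two
#' empty masks are in perfect agreement and score 1.
#'
#' @param a,b Binary 0/1 matrices of equal dimensions.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask dimensions differ", call. = FALSE)
  sa <- sum(a == 1); sb <- sum(b == 1)
  if (sa + sb == 0) return(1)
  2 * sum(a == 1 & b == 1) / (sa + sb)
}
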