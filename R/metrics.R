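#' Confusion counts for binary predictions
#'
#' @param pred Binary (0/1) predicted labels.
#' @param truth Binary (0/1) true labels, same length; 1 is the positive
#'   class.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth) {
  check_binary(pred, "pred")
  check_binary(truth, "truth")
  if (length(pred) != length(truth)) {
    abort("pred and truth must have equal length")
  }
  if (length(pred) == 0L) abort("need at least one prediction")
  tibble::tibble(
    tp = sum(pred == 1L & truth == 1L),
    fp = sum(pred == 1L & truth == 0L),
    fn = sum(pred == 0L & truth == 1L),
    tn = sum(pred == 0L & truth == 0L)
  )
}

check_binary <- function(x, what) {
  if (!is.numeric(x) && !is.logical(x)) {
    abort(paste0(what, " must be numeric 0/1"))
  }
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    abort(paste0(what, " must contain only 0 and 1"))
  }
  invisible(x)
}

#' The six-metric evaluation panel
#'
#' Computes accuracy, precision, recall, F1 and Matthews correlation
#' coefficient from confusion counts, plus rank-based ROC AUC and
#' step-interpolated precision-recall AUC when scores are supplied.  Any
#' metric whose defining ratio is 0/0 (e.g. precision with no positive
#' predictions) is reported as 0 and listed in the `degenerate` column;
#' AUC on a label-only (hard 0/1 score) predictor is flagged the same way.
#'
#' @param counts One-row tibble from [confusion_counts()].
#' @param scores Optional positive-class scores in `[0, 1]`.
#' @param truth Optional true labels matching `scores` (required with
#'   `scores`).
#' @return A one-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `mcc`, `auc`, `auprc`, `degenerate` (comma-separated flags, `""` if
#'   none).
#' @export
compute_metrics <- function(counts, scores = NULL, truth = NULL) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)), nrow(counts) == 1L)
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  tn <- counts$tn
  n <- tp + fp + fn + tn
  degenerate <- character()

  safe_ratio <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }

  accuracy <- safe_ratio(tp + tn, n, "accuracy")
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    degenerate <- c(degenerate, "f1")
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    degenerate <- c(degenerate, "mcc")
    0
  } else {
    (tp * tn - fp * fn) / mcc_den
  }

  auc <- NA_real_
  auprc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(truth)) abort("truth is required when scores are given")
    if (length(unique(truth)) < 2L) {
      degenerate <- c(degenerate, "auc", "auprc")
    } else {
      auc <- roc_auc(scores, truth)
      auprc <- pr_auc(scores, truth)
      if (all(scores %in% c(0, 1))) {
        degenerate <- c(degenerate, "auc_label_only")
      }
    }
  }

  tibble::tibble(
    accuracy = accuracy, precision = precision, recall = recall,
    f1 = f1, mcc = mcc, auc = auc, auprc = auprc,
    degenerate = paste(degenerate, collapse = ",")
  )
}

#' Rank-based area under the ROC curve
#'
#' The probability that a uniformly drawn positive outscores a uniformly
#' drawn negative, with ties counting one half — the Mann-Whitney
#' formulation, identical to trapezoidal integration of the ROC curve.
#'
#' @param scores Real-valued scores (higher = more positive).
#' @param truth Binary true labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  check_binary(truth, "truth")
  if (length(scores) != length(truth)) abort("scores and truth must align")
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0L || n_neg == 0L) {
    abort("roc_auc needs both classes present")
  }
  r <- rank(scores) # average ranks handle ties as 1/2
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation: thresholds sweep the distinct scores from high
#' to low and each recall increment contributes at the precision reached
#' there (the average-precision convention).
#'
#' @inheritParams roc_auc
#' @return AUPRC in `[0, 1]`.
#' @export
pr_auc <- function(scores, truth) {
  check_binary(truth, "truth")
  if (length(scores) != length(truth)) abort("scores and truth must align")
  n_pos <- sum(truth == 1)
  if (n_pos == 0L || n_pos == length(truth)) {
    abort("pr_auc needs both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # evaluate only at the last index of each tied score block
  last_of_block <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- tp[last_of_block]
  fp <- fp[last_of_block]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

#' Evaluate a prediction set against true labels
#'
#' Convenience wrapper joining a predictions tibble (`id`, `label`,
#' `score`) to truth and running the full panel.
#'
#' @param predictions Tibble with `id`, `label` (0/1) and `score`.
#' @param truth Tibble with `id` and `label`, or a bare 0/1 vector aligned
#'   to `predictions`.
#' @return A one-row metric tibble (see [compute_metrics()]).
#' @export
evaluate_predictions <- function(predictions, truth) {
  stopifnot(all(c("label", "score") %in% names(predictions)))
  if (is.data.frame(truth)) {
    stopifnot(all(c("id", "label") %in% names(truth)))
    m <- match(predictions$id, truth$id)
    if (anyNA(m)) {
      abort(paste0(
        "prediction id(s) missing from truth: ",
        paste(head(predictions$id[is.na(m)], 5L), collapse = ", ")
      ))
    }
    y <- as.integer(truth$label[m])
  } else {
    y <- as.integer(truth)
  }
  compute_metrics(
    confusion_counts(predictions$label, y),
    scores = predictions$score, truth = y
  )
}
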