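#' Majority vote over the three classical labels
#'
#' `lmv = 1` iff at least two of the SVM, RF and KNN labels are 1.
#' Vectorised over aligned label vectors.
#'
#' @param ls,lr,lk Binary (0/1) labels from the SVM, RF and KNN models.
#' @return Integer 0/1 vector.
#' @export
majority_vote <- function(ls, lr, lk) {
  check_binary(ls, "ls")
  check_binary(lr, "lr")
  check_binary(lk, "lk")
  as.integer(ls + lr + lk >= 2)
}

#' Combined classical decision f(t)
#'
#' Computed exactly as defined: `f(t) = lmv AND (ls OR lr OR lk)`.  Note
#' the conjunct is redundant — a majority of three ones implies at least
#' one one, so `f(t)` is identical to `lmv` on all eight input
#' combinations; the formula is evaluated as written rather than
#' simplified.
#'
#' @inheritParams majority_vote
#' @return Integer 0/1 vector.
#' @export
mla_combined_decision <- function(ls, lr, lk) {
  lmv <- majority_vote(ls, lr, lk)
  as.integer((lmv == 1L) & (ls == 1L | lr == 1L | lk == 1L))
}

#' The deep hybrid learning decision
#'
#' Final decision-level fusion: the combined classical decision `f(t)` is
#' ORed with the deep classifier's label, so an example is called a loop
#' when either route says so.
#'
#' @inheritParams majority_vote
#' @param d Binary label(s) from the deep classifier.
#' @return A tibble with columns `lmv`, `f_t`, `final`.
#' @export
dhl_decision <- function(ls, lr, lk, d) {
  check_binary(d, "d")
  lmv <- majority_vote(ls, lr, lk)
  f_t <- mla_combined_decision(ls, lr, lk)
  tibble::tibble(
    lmv = lmv, f_t = f_t,
    final = as.integer(d == 1L | f_t == 1L)
  )
}

#' Fuse four prediction sets into the hybrid decision
#'
#' Element-wise [dhl_decision()] over aligned prediction sets.  The four
#' inputs must cover identical example ids; rows are aligned to the SVM
#' set's order.  Because fusion operates on hard labels, the fused score
#' is defined as the fused label itself (ROC AUC on the fused output is
#' therefore degenerate and flagged as such by [compute_metrics()]).
#'
#' @param svm,rf,knn,deep Prediction tibbles (`id`, `label`, `score`).
#' @return A tibble: `id`, `lmv`, `f_t`, `label` (the hybrid decision)
#'   and `score` (== `label`).
#' @export
fuse_predictions <- function(svm, rf, knn, deep) {
  sets <- list(svm = svm, rf = rf, knn = knn, deep = deep)
  for (nm in names(sets)) {
    stopifnot(all(c("id", "label") %in% names(sets[[nm]])))
  }
  ids <- svm$id
  for (nm in c("rf", "knn", "deep")) {
    other <- sets[[nm]]$id
    divergent <- c(setdiff(ids, other), setdiff(other, ids))
    if (length(divergent) > 0L) {
      abort(paste0(
        "prediction sets disagree on example ids (", nm, " vs svm): ",
        paste(head(divergent, 10L), collapse = ", "),
        if (length(divergent) > 10L) paste0(" (+", length(divergent) - 10L, " more)") else ""
      ))
    }
  }
  if (length(ids) == 0L) {
    return(tibble::tibble(
      id = character(), lmv = integer(), f_t = integer(),
      label = integer(), score = numeric()
    ))
  }
  ls <- as.integer(svm$label)
  lr <- as.integer(rf$label[match(ids, rf$id)])
  lk <- as.integer(knn$label[match(ids, knn$id)])
  d <- as.integer(deep$label[match(ids, deep$id)])
  dec <- dhl_decision(ls, lr, lk, d)
  tibble::tibble(
    id = ids, lmv = dec$lmv, f_t = dec$f_t,
    label = dec$final, score = as.numeric(dec$final)
  )
}
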