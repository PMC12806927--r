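#' Specification of a classical classifier
#'
#' The three classical learners of the hybrid: a radial-basis support
#' vector machine with probability calibration, a random forest whose
#' score is the tree-vote fraction, and a k-nearest-neighbour classifier
#' whose score is the neighbour-vote fraction.  Defaults: SVM `cost = 1`
#' with e1071's `1/p` gamma; RF 100 trees; KNN 5 neighbours, Euclidean
#' metric.
#'
#' @param algorithm One of `"svm"`, `"rf"`, `"knn"`.
#' @param ... Hyperparameter overrides (`cost`, `gamma` for svm; `ntree`,
#'   `mtry` for rf; `neighbors` for knn).
#' @param seed Integer seed making training (and KNN tie-breaking)
#'   deterministic.
#' @return A list of class `dhl_classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("svm", "rf", "knn"), ..., seed = 1L) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    svm = list(cost = 1, gamma = NULL),
    rf = list(ntree = 100L, mtry = NULL),
    knn = list(neighbors = 5L)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste0(
      "unknown hyperparameter(s) for ", algorithm, ": ",
      paste(unknown, collapse = ", ")
    ))
  }
  hyper <- utils::modifyList(defaults, overrides)
  structure(
    list(algorithm = algorithm, hyperparameters = hyper, seed = as.integer(seed)),
    class = "dhl_classifier_spec"
  )
}

#' Train a classical classifier on pair features
#'
#' @param features Feature tibble from [pair_features()] (`id`, `label`,
#'   feature columns), containing both classes.
#' @param spec A [classifier_spec()].
#' @return A fitted model handle of class `dhl_classifier`; use
#'   [predict.dhl_classifier()] to score new examples.
#' @export
train_classifier <- function(features, spec = classifier_spec("svm")) {
  stopifnot(inherits(spec, "dhl_classifier_spec"))
  x <- feature_matrix(features)
  y <- as.integer(features$label)
  if (nrow(x) < 2L) abort("need at least 2 training examples")
  if (length(unique(y)) < 2L) {
    abort("training data must contain both classes")
  }
  fit <- withr::with_seed(spec$seed, {
    switch(spec$algorithm,
      svm = {
        h <- spec$hyperparameters
        args <- list(
          x = x, y = factor(y, levels = c(0L, 1L)),
          kernel = "radial", cost = h$cost, probability = TRUE
        )
        if (!is.null(h$gamma)) args$gamma <- h$gamma
        do.call(e1071::svm, args)
      },
      rf = {
        h <- spec$hyperparameters
        args <- list(
          x = x, y = factor(y, levels = c(0L, 1L)), ntree = h$ntree
        )
        if (!is.null(h$mtry)) args$mtry <- h$mtry
        do.call(randomForest::randomForest, args)
      },
      knn = list(x = x, y = y) # lazy learner: keep the training set
    )
  })
  structure(
    list(spec = spec, fit = fit, feature_names = colnames(x)),
    class = "dhl_classifier"
  )
}

#' @export
print.dhl_classifier <- function(x, ...) {
  cat("<dhl_classifier> ", x$spec$algorithm, ", ",
    length(x$feature_names), " features\n",
    sep = ""
  )
  invisible(x)
}

#' Predict loop labels with a fitted classical classifier
#'
#' Scores are positive-class probabilities (SVM) or vote fractions
#' (RF trees, KNN neighbours); hard labels are `score >= 0.5`.
#'
#' @param object A fitted [train_classifier()] handle.
#' @param features Feature tibble with the training feature columns.
#' @param ... Unused.
#' @return A prediction tibble: `id`, `label` (0/1), `score` in `[0, 1]`.
#' @export
predict.dhl_classifier <- function(object, features, ...) {
  x <- feature_matrix(features)
  if (nrow(x) == 0L) {
    return(tibble::tibble(id = character(), label = integer(), score = numeric()))
  }
  if (!identical(colnames(x), object$feature_names)) {
    abort("feature columns do not match the training features")
  }
  score <- switch(object$spec$algorithm,
    svm = {
      p <- predict(object$fit, x, probability = TRUE)
      attr(p, "probabilities")[, "1"]
    },
    rf = predict(object$fit, x, type = "prob")[, "1"],
    knn = withr::with_seed(object$spec$seed, {
      k <- object$spec$hyperparameters$neighbors
      pred <- class::knn(
        train = object$fit$x, test = x,
        cl = factor(object$fit$y, levels = c(0L, 1L)),
        k = k, prob = TRUE
      )
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    })
  )
  score <- unname(as.numeric(score))
  tibble::tibble(
    id = features$id,
    label = as.integer(score >= 0.5),
    score = score
  )
}

#' Stratified k-fold cross-validation
#'
#' Splits the examples into `n_folds` class-stratified folds (each
#' example tested exactly once), trains on the complement of each fold,
#' and evaluates the six-metric panel per fold.  The `average` element is
#' the arithmetic mean of the fold metrics, the form the fold-averaged
#' ("Avg") results are reported in.
#'
#' @param features Feature tibble (`id`, `label`, feature columns).
#' @param spec A [classifier_spec()].
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for fold assignment.
#' @return A list of class `dhl_cv`: `fold_metrics` (tibble with a `fold`
#'   column), `average` (one-row tibble), `assignments` (integer fold per
#'   example) and `spec`.
#' @export
cross_validate <- function(features, spec = classifier_spec("svm"),
                           n_folds = 5L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) abort("n_folds must be >= 2")
  y <- as.integer(features$label)
  if (min(table(factor(y, levels = c(0L, 1L)))) < n_folds) {
    abort("each class needs at least n_folds examples")
  }
  fold <- stratified_folds(y, n_folds, seed)
  fold_metrics <- purrr::map_dfr(seq_len(n_folds), function(f) {
    train <- features[fold != f, , drop = FALSE]
    test <- features[fold == f, , drop = FALSE]
    model <- train_classifier(train, spec)
    preds <- predict(model, test)
    dplyr::bind_cols(
      tibble::tibble(fold = f),
      evaluate_predictions(preds, as.integer(test$label))
    )
  })
  numeric_cols <- c("accuracy", "precision", "recall", "f1", "mcc", "auc", "auprc")
  average <- tibble::as_tibble(as.list(colMeans(fold_metrics[numeric_cols])))
  structure(
    list(
      fold_metrics = fold_metrics, average = average,
      assignments = fold, spec = spec
    ),
    class = "dhl_cv"
  )
}

# Class-stratified fold labels: within each class, shuffle then deal
# round-robin, so fold sizes per class differ by at most one.
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' @export
print.dhl_cv <- function(x, ...) {
  cat("<dhl_cv> ", x$spec$algorithm, ", ",
    nrow(x$fold_metrics), "-fold cross-validation\n",
    sep = ""
  )
  print(x$average)
  invisible(x)
}

#' @export
#' @method tidy dhl_cv
tidy.dhl_cv <- function(x, ...) {
  x$fold_metrics
}

#' @export
#' @method glance dhl_cv
glance.dhl_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(algorithm = x$spec$algorithm, n_folds = nrow(x$fold_metrics)),
    x$average
  )
}

#' @export
#' @method autoplot dhl_cv
autoplot.dhl_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$fold_metrics,
    cols = c("accuracy", "precision", "recall", "f1", "mcc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$fold), y = .data$value, group = .data$metric,
    colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "fold", y = "value",
      title = paste0(object$spec$algorithm, ": fold-wise performance")
    ) +
    ggplot2::theme_minimal()
}

#' Train on the whole training split ("WD" mode)
#'
#' Whole-data training: a single model fit on the full training split,
#' intended to be evaluated only on the chromosome holdout — the mode that
#' puts the classical learners on an equal footing with the deep
#' classifier, and the model carried into decision fusion.
#'
#' @inheritParams train_classifier
#' @return A fitted `dhl_classifier` handle.
#' @export
train_whole_data <- function(features, spec = classifier_spec("svm")) {
  train_classifier(features, spec)
}
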