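#' Full pipeline configuration
#'
#' Bundles the per-stage settings of the end-to-end run.  One global
#' `seed` deterministically derives every stage seed (simulation, negative
#' sampling, fold assignment, each learner), so two runs with the same
#' configuration are identical.
#'
#' @param sim A [sim_config()]; set to `NULL` when supplying a real
#'   genome/loops via `run_dhl_pipeline(genome =, positives =)`.
#' @param dataset A [dataset_config()].
#' @param k k-mer width shared by the feature and token representations.
#' @param normalize Use k-mer frequencies (`TRUE`) or raw counts.
#' @param svm,rf,knn [classifier_spec()]s for the three classical models
#'   (their seeds are overridden by the derived stage seeds).
#' @param finetune A [fine_tune_config()] for the deep stand-in.
#' @param n_folds Cross-validation folds.
#' @param seed Global seed.
#' @return A list of class `dhl_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            dataset = dataset_config(),
                            k = 3L,
                            normalize = TRUE,
                            svm = classifier_spec("svm"),
                            rf = classifier_spec("rf"),
                            knn = classifier_spec("knn"),
                            finetune = fine_tune_config(),
                            n_folds = 5L,
                            seed = 1L) {
  structure(
    list(
      sim = sim, dataset = dataset, k = as.integer(k), normalize = normalize,
      svm = svm, rf = rf, knn = knn, finetune = finetune,
      n_folds = as.integer(n_folds), seed = as.integer(seed)
    ),
    class = "dhl_pipeline_config"
  )
}

#' Run the deep hybrid learning pipeline end to end
#'
#' Executes every stage in order: simulate (or accept) a genome and
#' positive loop set; build the balanced, chromosome-holdout dataset;
#' featurise with overlapping k-mers; cross-validate and whole-data-train
#' the three classical models; train the deep stand-in (or import
#' external deep predictions); fuse the four holdout label sets with the
#' majority-vote/OR rule; and evaluate the six-metric panel for every
#' route.
#'
#' @param config A [pipeline_config()].
#' @param genome Optional genome overriding simulation.
#' @param positives Optional positive loop tibble overriding simulation
#'   (required with `genome`).
#' @param deep_predictions Optional externally produced holdout
#'   predictions (`id`, `label`, `score`) used instead of the stand-in.
#' @return A list of class `dhl_result`: `holdout` (seven-row metric
#'   panel: svm, rf, knn, deep, lmv, f_t, dhl), `cv` (per-algorithm
#'   [cross_validate()] results), `predictions` (per-example holdout
#'   labels/scores incl. fused columns), `dataset` (the built
#'   `dhl_dataset`) and `config`.
#' @export
run_dhl_pipeline <- function(config = pipeline_config(),
                             genome = NULL, positives = NULL,
                             deep_predictions = NULL) {
  stopifnot(inherits(config, "dhl_pipeline_config"))
  seed <- config$seed

  if (is.null(genome)) {
    if (is.null(config$sim)) abort("config$sim is NULL and no genome was supplied")
    sim_cfg <- config$sim
    sim_cfg$seed <- derive_seed(seed, "simulate")
    sim <- plant_loops(simulate_genome(sim_cfg), sim_cfg)
    genome <- sim$genome
    positives <- sim$positives
  } else if (is.null(positives)) {
    abort("positives are required when a genome is supplied")
  }

  ds_cfg <- config$dataset
  ds_cfg$seed <- derive_seed(seed, "negatives")
  dataset <- build_dataset(genome, positives, ds_cfg)
  if (nrow(dataset$train) == 0L || nrow(dataset$test) == 0L) {
    abort("pipeline: empty train or test split after dataset construction")
  }

  feats_train <- pair_features(dataset$train, k = config$k, normalize = config$normalize)
  feats_test <- pair_features(dataset$test, k = config$k, normalize = config$normalize)

  algos <- c("svm", "rf", "knn")
  cv <- list()
  holdout_preds <- list()
  for (algo in algos) {
    spec <- config[[algo]]
    spec$seed <- derive_seed(seed, paste0("train-", algo))
    cv[[algo]] <- cross_validate(
      feats_train, spec,
      n_folds = config$n_folds,
      seed = derive_seed(seed, paste0("folds-", algo))
    )
    model <- train_whole_data(feats_train, spec)
    holdout_preds[[algo]] <- predict(model, feats_test)
  }

  if (is.null(deep_predictions)) {
    deep_model <- train_standin(
      dataset$train, config$finetune,
      k = config$k, seed = derive_seed(seed, "deep")
    )
    holdout_preds$deep <- predict(deep_model, dataset$test)
  } else {
    holdout_preds$deep <- import_external_predictions_tbl(
      deep_predictions, dataset$test$id
    )
  }

  fused <- fuse_predictions(
    holdout_preds$svm, holdout_preds$rf, holdout_preds$knn, holdout_preds$deep
  )
  truth <- as.integer(dataset$test$label)

  panel <- dplyr::bind_rows(
    row_metrics("svm", holdout_preds$svm, truth),
    row_metrics("rf", holdout_preds$rf, truth),
    row_metrics("knn", holdout_preds$knn, truth),
    row_metrics("deep", holdout_preds$deep, truth),
    row_metrics("lmv", pred_from_labels(fused$id, fused$lmv), truth),
    row_metrics("f_t", pred_from_labels(fused$id, fused$f_t), truth),
    row_metrics("dhl", pred_from_labels(fused$id, fused$label), truth)
  )

  predictions <- tibble::tibble(
    id = fused$id,
    truth = truth,
    svm = holdout_preds$svm$label,
    rf = holdout_preds$rf$label,
    knn = holdout_preds$knn$label,
    deep = holdout_preds$deep$label,
    lmv = fused$lmv, f_t = fused$f_t, dhl = fused$label
  )

  structure(
    list(
      holdout = panel, cv = cv, predictions = predictions,
      dataset = dataset, config = config
    ),
    class = "dhl_result"
  )
}

row_metrics <- function(name, preds, truth) {
  dplyr::bind_cols(
    tibble::tibble(classifier = name),
    evaluate_predictions(preds, truth)
  )
}

pred_from_labels <- function(id, label) {
  tibble::tibble(id = id, label = as.integer(label), score = as.numeric(label))
}

import_external_predictions_tbl <- function(preds, expected_ids) {
  stopifnot(all(c("id", "label", "score") %in% names(preds)))
  missing <- setdiff(expected_ids, preds$id)
  if (length(missing) > 0L) {
    abort(paste0(
      "external deep predictions missing id(s): ",
      paste(head(missing, 10L), collapse = ", ")
    ))
  }
  preds[match(expected_ids, preds$id), , drop = FALSE]
}

#' @export
print.dhl_result <- function(x, ...) {
  cat("<dhl_result> holdout panel (", nrow(x$predictions), " examples):\n", sep = "")
  print(x$holdout, n = nrow(x$holdout))
  invisible(x)
}

#' @export
#' @method tidy dhl_result
tidy.dhl_result <- function(x, ...) {
  x$holdout
}

#' @export
#' @method glance dhl_result
glance.dhl_result <- function(x, ...) {
  dhl <- x$holdout[x$holdout$classifier == "dhl", ]
  dplyr::bind_cols(
    tibble::tibble(
      n_train = nrow(x$dataset$train),
      n_test = nrow(x$dataset$test)
    ),
    dhl[setdiff(names(dhl), "classifier")]
  )
}

#' Plot the holdout metric panel
#'
#' Grouped bars of accuracy, precision, recall, F1 and MCC per
#' classifier, the layout of a holdout performance figure.
#'
#' @param object A `dhl_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot dhl_result
autoplot.dhl_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$holdout,
    cols = c("accuracy", "precision", "recall", "f1", "mcc"),
    names_to = "metric", values_to = "value"
  )
  long$classifier <- factor(long$classifier, levels = unique(object$holdout$classifier))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$classifier, y = .data$value, fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "value", title = "Holdout performance") +
    ggplot2::theme_minimal()
}

#' Write a pipeline report to JSON and TSV
#'
#' Serialises the holdout panel and cross-validation averages
#' deterministically (stable column order, full precision), so identical
#' runs produce byte-identical reports.
#'
#' @param result A `dhl_result`.
#' @param json_path Output JSON path (`NULL` to skip).
#' @param tsv_path Output TSV path (`NULL` to skip).
#' @return The result, invisibly.
#' @export
write_report <- function(result, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(result, "dhl_result"))
  if (!is.null(json_path)) {
    cv_avg <- purrr::map(result$cv, function(cv) as.list(cv$average))
    jsonlite::write_json(
      list(
        holdout = result$holdout,
        cv_average = cv_avg,
        n_train = nrow(result$dataset$train),
        n_test = nrow(result$dataset$test)
      ),
      json_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
  }
  if (!is.null(tsv_path)) {
    utils::write.table(
      result$holdout, tsv_path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(result)
}
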