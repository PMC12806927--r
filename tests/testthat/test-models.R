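test_that("all three algorithms separate two distant clusters perfectly", {
  feats <- separable_features()
  for (algo in c("svm", "rf", "knn")) {
    model <- train_classifier(feats, classifier_spec(algo, seed = 1L))
    preds <- predict(model, feats)
    expect_equal(mean(preds$label == feats$label), 1.0, info = algo)
  }
})

test_that("1-NN predicts its own training set perfectly", {
  feats <- separable_features()
  model <- train_classifier(feats, classifier_spec("knn", neighbors = 1L))
  preds <- predict(model, feats)
  expect_equal(preds$label, feats$label)
})

test_that("training rejects single-class or too-small input", {
  feats <- separable_features()
  one_class <- feats[feats$label == 1L, ]
  for (algo in c("svm", "rf", "knn")) {
    expect_error(
      train_classifier(one_class, classifier_spec(algo)),
      "both classes"
    )
  }
  expect_error(train_classifier(feats[1, ], classifier_spec("svm")), "at least 2")
  expect_error(classifier_spec("svm", bogus = 1), "unknown hyperparameter")
})

test_that("training and prediction are deterministic given the seed", {
  cfg0 <- sim_config(n_chromosomes = 2L, chrom_length = 80000L, n_loops = 50L, seed = 31L)
  sim <- plant_loops(simulate_genome(cfg0), cfg0)
  ds <- suppressMessages(build_dataset(
    sim$genome, sim$positives,
    dataset_config(max_distance = 60000L, holdout_chromosomes = character(), seed = 4L)
  ))
  feats <- pair_features(ds$train)
  for (algo in c("svm", "rf", "knn")) {
    spec <- classifier_spec(algo, seed = 11L)
    p1 <- predict(train_classifier(feats, spec), feats)
    p2 <- predict(train_classifier(feats, spec), feats)
    expect_identical(p1, p2, info = algo)
  }
})

test_that("prediction labels are the 0.5 threshold of scores, empty in empty out", {
  feats <- separable_features()
  model <- train_classifier(feats, classifier_spec("rf", seed = 2L))
  withr::with_seed(7L, {
    noise <- feats
    for (cn in paste0("f", 1:4)) noise[[cn]] <- stats::rnorm(nrow(feats), 1.5, 2)
  })
  preds <- predict(model, noise)
  expect_identical(preds$label, as.integer(preds$score >= 0.5))
  expect_true(all(preds$score >= 0 & preds$score <= 1))

  empty <- feats[0, ]
  expect_equal(nrow(predict(model, empty)), 0L)

  expect_error(predict(model, feats[, 1:4]), "feature columns")
})

test_that("5-fold cross-validation is stratified and partitions each example once", {
  cfg0 <- sim_config(n_chromosomes = 2L, chrom_length = 80000L, n_loops = 60L, seed = 41L)
  sim <- plant_loops(simulate_genome(cfg0), cfg0)
  ds <- suppressMessages(build_dataset(
    sim$genome, sim$positives,
    dataset_config(max_distance = 60000L, holdout_chromosomes = character(), seed = 6L)
  ))
  feats <- pair_features(ds$train)
  cv <- cross_validate(feats, classifier_spec("rf", seed = 3L), n_folds = 5L, seed = 8L)

  expect_equal(nrow(cv$fold_metrics), 5L)
  expect_length(cv$assignments, nrow(feats))
  expect_setequal(unique(cv$assignments), 1:5)
  # every example in exactly one fold, fold sizes near-equal
  expect_equal(sum(table(cv$assignments)), nrow(feats))
  expect_lte(diff(range(table(cv$assignments))), 2L)
  # stratification: per-fold positive fraction within 1/n_folds of global
  global <- mean(feats$label)
  for (f in 1:5) {
    expect_lte(abs(mean(feats$label[cv$assignments == f]) - global), 1 / 5)
  }
  # the average is the arithmetic mean of folds
  expect_equal(cv$average$accuracy, mean(cv$fold_metrics$accuracy), tolerance = 1e-12)
  expect_equal(cv$average$mcc, mean(cv$fold_metrics$mcc), tolerance = 1e-12)

  # tidiers expose folds and summary
  expect_equal(nrow(tidy(cv)), 5L)
  expect_equal(glance(cv)$algorithm, "rf")
})

test_that("cross-validation on label-shuffled data is at chance level", {
  withr::with_seed(53L, {
    n <- 200L
    m <- matrix(stats::rnorm(n * 8L), ncol = 8L)
    colnames(m) <- paste0("f", 1:8)
    feats <- dplyr::bind_cols(
      tibble::tibble(id = paste0("ex", 1:n), label = sample(rep(0:1, each = n / 2))),
      tibble::as_tibble(m)
    )
  })
  cv <- cross_validate(feats, classifier_spec("knn", seed = 5L), seed = 9L)
  band <- 3 * sqrt(0.25 / 200) # 3 sigma of a fair coin over all examples
  expect_lt(abs(cv$average$accuracy - 0.5), band + 0.05)
})

test_that("whole-data training shares the prediction and report schema with CV", {
  feats <- separable_features()
  model <- train_whole_data(feats, classifier_spec("svm", seed = 1L))
  preds <- predict(model, feats)
  report <- evaluate_predictions(preds, as.integer(feats$label))
  cv <- cross_validate(feats, classifier_spec("svm", seed = 1L), seed = 2L)
  expect_setequal(
    names(report),
    setdiff(names(cv$fold_metrics), "fold")
  )
  expect_equal(report$accuracy, 1.0)
})
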