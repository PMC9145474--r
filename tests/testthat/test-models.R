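lex <- default_lexicon()

# small labeled feature set with a clean signal, shared across blocks
sep_cohort <- make_separable_cohort(n_cases = 20, n_controls = 30)
sep_features <- build_feature_matrix(sep_cohort, lex)
sep_labels <- data.frame(patient_id = sep_cohort$truth$patient_id,
                         label = sep_cohort$truth$truth_label)

test_that("stratified folds keep class ratios within one patient", {
  set.seed(83)
  for (r in 1:10) {
    n <- sample(40:200, 1)
    y <- rbinom(n, 1, runif(1, 0.15, 0.5))
    if (length(unique(y)) < 2) next
    k <- sample(3:10, 1)
    folds <- pahphen:::stratified_folds(y, k, repeats = 2)
    expect_length(folds, 2 * k)
    pos_counts <- vapply(folds[1:k], function(f) sum(y[f]), integer(1))
    expect_lte(max(pos_counts) - min(pos_counts), 1L)
    sizes <- vapply(folds[1:k], length, integer(1))
    expect_equal(sum(sizes), n)
  }
})

test_that("all three algorithm families separate a clean signal", {
  for (alg in c("random_forest", "xgboost", "elastic_net")) {
    m <- train_model(sep_features, sep_labels, small_model_config(alg))
    expect_s3_class(m, "pah_model")
    expect_length(m$cv_auc_samples, 3L)  # folds x repeats
    expect_equal(mean(m$cv_auc_samples), 1.0)
  }
})

test_that("training rejects degenerate inputs", {
  one_class <- sep_labels
  one_class$label <- "PAH"
  expect_error(train_model(sep_features, one_class,
                           small_model_config("random_forest")),
               "single class")
  expect_error(train_model(sep_features, rep("PAH", 3),
                           small_model_config("random_forest")),
               "length mismatch")
})

test_that("cross-validated AUC is near 1/2 under label permutation", {
  set.seed(89)
  n <- 500
  x <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  for (s in 1:8) {
    y_null <- sample(rep(0:1, c(300, 200)))
    folds <- pahphen:::stratified_folds(y_null, 5, 1)
    aucs <- pahphen:::cv_fold_aucs(
      "random_forest", x, y_null,
      list(num_trees = 200, mtry_frac = 0.3, min_node = 5), folds, seed = s)
    expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.08)
  }
})

test_that("more optimization iterations never cost material accuracy", {
  lean <- train_model(sep_features, sep_labels,
                      small_model_config("xgboost", opt_init = 1L,
                                         opt_iterations = 0L))
  tuned <- train_model(sep_features, sep_labels,
                       small_model_config("xgboost", opt_init = 3L,
                                          opt_iterations = 3L))
  expect_gte(mean(tuned$cv_auc_samples), mean(lean$cv_auc_samples) - 0.02)
})

test_that("prediction is deterministic, thresholded, and schema-checked", {
  m <- train_model(sep_features, sep_labels,
                   small_model_config("random_forest"))
  p1 <- predict(m, sep_features)
  p2 <- predict(m, sep_features)
  expect_identical(p1, p2)
  expect_true(all(p1$score >= 0 & p1$score <= 1))

  # zeros were the control signature in training, so an all-zero row is
  # labeled not_PAH
  zero <- sep_features[1, ]
  zero[, -1] <- 0
  expect_equal(predict(m, zero)$label, "not_PAH")

  # a degenerate zero threshold labels everything positive
  expect_true(all(predict(m, sep_features, threshold = 0)$label == "PAH"))

  broken <- sep_features[, -2]
  expect_error(predict(m, broken), "schema mismatch")
  extra <- sep_features
  extra$bogus <- 1
  expect_error(predict(m, extra), "schema mismatch")
})

test_that("training is reproducible under a fixed seed", {
  a <- train_model(sep_features, sep_labels,
                   small_model_config("elastic_net", seed = 7L))
  b <- train_model(sep_features, sep_labels,
                   small_model_config("elastic_net", seed = 7L))
  expect_identical(a$hyperparameters, b$hyperparameters)
  expect_identical(predict(a, sep_features)$score,
                   predict(b, sep_features)$score)
})

test_that("permutation importance recovers the discriminating feature", {
  # one informative column among pure noise: permutation importance must put
  # it first and cannot rank noise above it
  set.seed(113)
  n <- 120
  y <- rep(c("PAH", "not_PAH"), each = n / 2)
  feats <- data.frame(
    patient_id = sprintf("Q%03d", seq_len(n)),
    signal = as.numeric(y == "PAH") * 3 + rnorm(n),
    check.names = FALSE)
  for (j in 1:5) feats[[paste0("noise", j)]] <- rnorm(n)
  m <- train_model(feats, y, small_model_config("random_forest"))
  imp <- feature_importance(m, feats, y, seed = 3)
  expect_equal(nrow(imp), length(m$feature_names))
  expect_equal(imp$feature[1], "signal")
  expect_true(all(imp$importance[imp$feature != "signal"] <=
                    imp$importance[1]))
})
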