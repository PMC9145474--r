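#' Training configuration for the claims-based classifiers
#'
#' Three model families are supported, mirroring standard practice for
#' computable-phenotype classifiers: random forests (via \pkg{ranger}),
#' extreme gradient boosting (via \pkg{xgboost}) and elastic-net logistic
#' regression (via \pkg{glmnet}). Hyperparameters are selected by
#' [bayes_optimize()] maximizing the mean area under the curve (AUC) over
#' stratified k-fold cross-validation repeated `cv_repeats` times; the final
#' model is then refit on the entire training set at the optimum.
#'
#' @param algorithm one of `random_forest`, `xgboost`, `elastic_net`.
#' @param cv_folds number of cross-validation folds (default 10).
#' @param cv_repeats number of repeats (default 3, giving 30 fold AUCs).
#' @param opt_init random (Latin-hypercube) initial evaluations.
#' @param opt_iterations expected-improvement iterations after the design.
#' @param search_space per-algorithm bounds; `NULL` uses
#'   [default_search_space()].
#' @param threshold probability cutoff for the positive class.
#' @param seed integer seed; training is deterministic given it.
#' @return a `training_config` object.
#' @export
training_config <- function(algorithm = c("random_forest", "xgboost",
                                          "elastic_net"),
                            cv_folds = 10L, cv_repeats = 3L,
                            opt_init = 10L, opt_iterations = 30L,
                            search_space = NULL, threshold = 0.5,
                            seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(cv_folds >= 2L, cv_repeats >= 1L,
            threshold > 0, threshold < 1, opt_init >= 1L)
  structure(
    list(algorithm = algorithm, cv_folds = as.integer(cv_folds),
         cv_repeats = as.integer(cv_repeats),
         opt_init = as.integer(opt_init),
         opt_iterations = as.integer(opt_iterations),
         search_space = search_space %||% default_search_space(algorithm),
         threshold = threshold, seed = as.integer(seed)),
    class = "training_config"
  )
}

#' @rdname training_config
#' @export
default_search_space <- function(algorithm) {
  switch(algorithm,
    random_forest = list(
      num_trees = list(lower = 200, upper = 1000, integer = TRUE),
      mtry_frac = list(lower = 0.05, upper = 1.0),
      min_node  = list(lower = 1, upper = 20, integer = TRUE)
    ),
    xgboost = list(
      eta       = list(lower = 0.01, upper = 0.3),
      max_depth = list(lower = 2, upper = 8, integer = TRUE),
      nrounds   = list(lower = 50, upper = 500, integer = TRUE),
      subsample = list(lower = 0.5, upper = 1.0)
    ),
    elastic_net = list(
      alpha  = list(lower = 0, upper = 1),
      lambda = list(lower = 1e-4, upper = 10, log = TRUE)
    ),
    stop("unknown algorithm: ", algorithm)
  )
}

# stratified fold assignment: per class, shuffle then deal round-robin, so
# every fold's class count is within 1 of every other fold's
stratified_folds <- function(y01, k, repeats) {
  lapply(seq_len(repeats), function(r) {
    fold <- integer(length(y01))
    for (cls in unique(y01)) {
      idx <- sample(which(y01 == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    lapply(seq_len(k), function(f) which(fold == f))
  }) |> unlist(recursive = FALSE)
}

fit_algorithm <- function(algorithm, x, y01, params, seed) {
  switch(algorithm,
    random_forest = {
      p <- ncol(x)
      ranger::ranger(
        x = x, y = factor(y01, levels = c(0L, 1L)),
        probability = TRUE,
        num.trees = params$num_trees,
        mtry = max(1L, min(p, as.integer(round(params$mtry_frac * p)))),
        min.node.size = params$min_node,
        seed = seed, num.threads = 1L)
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y01)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = params$eta, max_depth = params$max_depth,
                      subsample = params$subsample,
                      nthread = 1L, seed = seed),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
    },
    elastic_net = {
      # fit the full regularization path (warm starts, early stopping) and
      # interpolate predictions at the tuned lambda: the stable way to use
      # glmnet, even when the classes are separable
      fit <- glmnet::glmnet(x, y01, family = "binomial",
                            alpha = params$alpha)
      attr(fit, "tuned_lambda") <- params$lambda
      fit
    },
    stop("unknown algorithm: ", algorithm)
  )
}

score_algorithm <- function(algorithm, fit, x) {
  switch(algorithm,
    random_forest = {
      pr <- predict(fit, data = x, num.threads = 1L)$predictions
      as.numeric(pr[, "1"])
    },
    xgboost = as.numeric(predict(fit, xgboost::xgb.DMatrix(x))),
    elastic_net = as.numeric(predict(
      fit, newx = x, type = "response",
      s = max(attr(fit, "tuned_lambda"), min(fit$lambda))))
  )
}

cv_fold_aucs <- function(algorithm, x, y01, params, folds, seed) {
  vapply(folds, function(test_idx) {
    ytr <- y01[-test_idx]; yte <- y01[test_idx]
    if (length(unique(yte)) < 2L || length(unique(ytr)) < 2L) return(NA_real_)
    fit <- fit_algorithm(algorithm, x[-test_idx, , drop = FALSE], ytr,
                         params, seed)
    s <- score_algorithm(algorithm, fit, x[test_idx, , drop = FALSE])
    auc_score(s, ifelse(yte == 1L, "PAH", "not_PAH"))
  }, numeric(1L))
}

# align a labels argument (data.frame of patient_id/label, or plain vector)
# with a feature table
align_labels <- function(features, labels) {
  if (is.data.frame(labels)) {
    if (!all(c("patient_id", "label") %in% names(labels))) {
      stop("labels data.frame needs columns patient_id and label")
    }
    m <- match(features$patient_id, labels$patient_id)
    if (anyNA(m)) {
      stop("labels missing for ", sum(is.na(m)), " feature rows (e.g. ",
           features$patient_id[which(is.na(m))[1L]], ")")
    }
    as.character(labels$label[m])
  } else {
    if (length(labels) != nrow(features)) {
      stop("feature/label length mismatch (", nrow(features), " rows vs ",
           length(labels), " labels)")
    }
    as.character(labels)
  }
}

#' Train a tuned classifier on a labeled feature table
#'
#' Runs Gaussian-process Bayesian optimization of the algorithm's
#' hyperparameters, scoring each candidate by mean AUC over stratified
#' repeated cross-validation, then refits on all rows at the optimum. The
#' stored `cv_auc_samples` (one AUC per fold x repeat at the optimum) are the
#' basis of the training-set confidence intervals reported by
#' [resample_ci()].
#'
#' @param features data.frame with a `patient_id` column plus numeric feature
#'   columns (as from [build_feature_matrix()]).
#' @param labels data.frame (`patient_id`, `label`) or character vector
#'   aligned with `features`; both "PAH" and "not_PAH" must be present.
#' @param config a [training_config()].
#' @return a `pah_model`: algorithm name, tuned hyperparameters, fitted
#'   predictor, training column order, `cv_auc_samples`, threshold and seed.
#' @export
train_model <- function(features, labels, config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  lab <- align_labels(features, labels)
  if (length(unique(lab)) < 2L) {
    stop("training labels contain a single class (", unique(lab),
         "); both PAH and not_PAH are required")
  }
  y01 <- as.integer(lab == "PAH")
  x <- as.matrix(features[, setdiff(names(features), "patient_id"),
                          drop = FALSE])
  storage.mode(x) <- "double"
  set.seed(config$seed)
  folds <- stratified_folds(y01, config$cv_folds, config$cv_repeats)
  objective <- function(params) {
    mean(cv_fold_aucs(config$algorithm, x, y01, params, folds, config$seed),
         na.rm = TRUE)
  }
  opt <- bayes_optimize(objective, config$search_space,
                        n_init = config$opt_init,
                        n_iter = config$opt_iterations)
  cv_auc_samples <- cv_fold_aucs(config$algorithm, x, y01, opt$best_params,
                                 folds, config$seed)
  fit <- fit_algorithm(config$algorithm, x, y01, opt$best_params, config$seed)
  structure(
    list(algorithm = config$algorithm, hyperparameters = opt$best_params,
         fit = fit, feature_names = colnames(x),
         cv_auc_samples = cv_auc_samples, threshold = config$threshold,
         seed = config$seed, opt_history = opt$history),
    class = "pah_model"
  )
}

#' @export
print.pah_model <- function(x, ...) {
  ci <- resample_ci(x$cv_auc_samples[!is.na(x$cv_auc_samples)])
  cat("<pah_model> ", x$algorithm, ", ", length(x$feature_names),
      " features\n  cv AUC ", sprintf("%.3f (%.3f-%.3f)", ci[1L], ci[2L],
                                      ci[3L]),
      " over ", length(x$cv_auc_samples), " folds\n  hyperparameters: ",
      paste(names(x$hyperparameters),
            vapply(x$hyperparameters, function(v) format(v, digits = 3),
                   character(1L)),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Score new patients with a fitted model
#'
#' @param object a `pah_model`.
#' @param features feature table whose columns must match the training
#'   column set exactly (a schema error lists any difference).
#' @param threshold probability cutoff; defaults to the training config's.
#' @param ... unused.
#' @return data.frame: `patient_id`, `score` in `[0, 1]`, `label`
#'   ("PAH" iff score >= threshold).
#' @export
predict.pah_model <- function(object, features, threshold = NULL, ...) {
  threshold <- threshold %||% object$threshold
  cols <- setdiff(names(features), "patient_id")
  missing_cols <- setdiff(object$feature_names, cols)
  extra_cols <- setdiff(cols, object$feature_names)
  if (length(missing_cols) || length(extra_cols)) {
    stop("feature schema mismatch; missing: [",
         paste(utils::head(missing_cols, 5L), collapse = ", "),
         "], unexpected: [",
         paste(utils::head(extra_cols, 5L), collapse = ", "), "]")
  }
  x <- as.matrix(features[, object$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  s <- score_algorithm(object$algorithm, object$fit, x)
  data.frame(patient_id = as.character(features$patient_id), score = s,
             label = ifelse(s >= threshold, "PAH", "not_PAH"),
             stringsAsFactors = FALSE)
}

#' Permutation feature importance on held-out data
#'
#' Importance of a feature is the mean drop in held-out AUC when that
#' feature's column is permuted, averaged over `n_repeats` permutations —
#' comparable across the differently scaled strength/persistence/durability
#' features, unlike impurity importance. Sorted descending, ties broken by
#' feature name.
#'
#' @param model a `pah_model`.
#' @param features held-out feature table (schema-checked against the model).
#' @param labels held-out labels (data.frame or vector, as in
#'   [train_model()]).
#' @param n_repeats permutations per feature.
#' @param seed RNG seed for the permutations.
#' @return data.frame (`feature`, `importance`) ranked by importance.
#' @export
feature_importance <- function(model, features, labels, n_repeats = 5L,
                               seed = 1L) {
  stopifnot(inherits(model, "pah_model"))
  lab <- align_labels(features, labels)
  x <- as.matrix(features[, model$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  base_auc <- auc_score(score_algorithm(model$algorithm, model$fit, x), lab)
  set.seed(seed)
  drops <- vapply(model$feature_names, function(f) {
    mean(vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, f] <- sample(xp[, f])
      base_auc - auc_score(score_algorithm(model$algorithm, model$fit, xp),
                           lab)
    }, numeric(1L)))
  }, numeric(1L))
  out <- data.frame(feature = model$feature_names, importance = drops,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), ]
  rownames(out) <- NULL
  out
}
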