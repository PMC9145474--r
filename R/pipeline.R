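#' Stratified train/test split of a labeled cohort
#'
#' Per label stratum the test set receives `floor(test_fraction * n_stratum)`
#' patients and the training set the remainder; with 653 cases and 1041
#' non-cases at `test_fraction = 0.2` this yields the 338/1356 partition used
#' for final testing. Unstratified splits draw the test set from the pooled
#' ids.
#'
#' @param labels data.frame (`patient_id`, `label`).
#' @param test_fraction fraction held out for testing.
#' @param stratified split within each label stratum?
#' @param seed RNG seed.
#' @return a `cohort_split`: list with `train_ids`, `test_ids`,
#'   `test_fraction`, `stratified`, `seed`.
#' @export
#' @examples
#' labs <- data.frame(
#'   patient_id = sprintf("P%04d", 1:1694),
#'   label = rep(c("PAH", "not_PAH"), c(653, 1041)))
#' sp <- split_cohort(labs, test_fraction = 0.2, seed = 1)
#' length(sp$train_ids); length(sp$test_ids)  # 1356, 338
split_cohort <- function(labels, test_fraction, stratified = TRUE, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labels <- as.data.frame(labels)
  if (anyDuplicated(labels$patient_id)) stop("duplicate patient ids in labels")
  set.seed(seed)
  test_ids <- character()
  if (stratified) {
    for (cls in sort(unique(labels$label))) {
      ids <- labels$patient_id[labels$label == cls]
      n_test <- floor(test_fraction * length(ids))
      test_ids <- c(test_ids, sample(ids, n_test))
    }
  } else {
    test_ids <- sample(labels$patient_id,
                       floor(test_fraction * nrow(labels)))
  }
  train_ids <- setdiff(labels$patient_id, test_ids)
  stopifnot(length(intersect(train_ids, test_ids)) == 0L)
  structure(
    list(train_ids = sort(train_ids), test_ids = sort(test_ids),
         test_fraction = test_fraction, stratified = stratified, seed = seed),
    class = "cohort_split"
  )
}

algorithms <- c("random_forest", "xgboost", "elastic_net")

# evaluate a fitted model on a held-out labeled feature table
evaluate_model <- function(model, features, labels, threshold = NULL) {
  pred <- predict(model, features, threshold = threshold)
  lab <- align_labels(features, labels)
  tc <- confusion_metrics(pred$label, lab)
  tc$auc <- auc_score(pred$score, lab)
  tc
}

# train all three families on the training rows, evaluate each on the test
# rows, and select the winner by test AUC with ties broken in the fixed
# order RF > XGBoost > elastic net
train_and_select <- function(features, labels, split, config, threshold) {
  f_train <- features[features$patient_id %in% split$train_ids, , drop = FALSE]
  f_test <- features[features$patient_id %in% split$test_ids, , drop = FALSE]
  models <- list()
  chars <- list()
  for (alg in algorithms) {
    cfg <- training_config(
      algorithm = alg, cv_folds = config$cv_folds,
      cv_repeats = config$cv_repeats, opt_init = config$opt_init,
      opt_iterations = config$opt_iterations,
      search_space = config$search_spaces[[alg]],
      threshold = threshold, seed = config$seed)
    models[[alg]] <- train_model(f_train, labels, cfg)
    chars[[alg]] <- evaluate_model(models[[alg]], f_test, labels, threshold)
  }
  aucs <- vapply(chars, function(tc) tc$auc, numeric(1L))
  best <- algorithms[which.max(aucs[algorithms])]  # which.max: first max wins
  list(models = models, characteristics = chars, best_algorithm = best)
}

#' Multi-algorithm stage training configuration
#'
#' Shared knobs for the pipeline stages (each stage trains all three
#' algorithm families). Defaults follow the headline procedure — tenfold
#' cross-validation repeated 3 times, 30 optimization iterations — and can be
#' scaled down for desk-scale experiments.
#'
#' @param cv_folds,cv_repeats,opt_init,opt_iterations see
#'   [training_config()].
#' @param search_spaces optional named list of per-algorithm search spaces.
#' @param seed integer seed.
#' @return a `stage_training_config` list.
#' @export
stage_training_config <- function(cv_folds = 10L, cv_repeats = 3L,
                                  opt_init = 10L, opt_iterations = 30L,
                                  search_spaces = NULL, seed = 1L) {
  structure(
    list(cv_folds = as.integer(cv_folds), cv_repeats = as.integer(cv_repeats),
         opt_init = as.integer(opt_init),
         opt_iterations = as.integer(opt_iterations),
         search_spaces = search_spaces %||%
           stats::setNames(lapply(algorithms, default_search_space),
                           algorithms),
         seed = as.integer(seed)),
    class = "stage_training_config"
  )
}

#' Development stage: screen, rank, review, train the Initial Algorithm
#'
#' Screens the population, ranks flagged records by feature count,
#' adjudicates the top `review_budget` charts with the hemodynamic oracle,
#' builds strength/persistence/durability features for the reviewed cohort,
#' performs a stratified 70/30 split, trains all three algorithm families on
#' the training rows and selects the best by test AUC.
#'
#' @param cohort an `emr_cohort`.
#' @param lexicon a `pah_lexicon`.
#' @param rule an `adjudication_rule`.
#' @param review_budget number of charts the (simulated) reviewers can read.
#' @param config a [stage_training_config()].
#' @param test_fraction held-out fraction (default 0.3).
#' @param threshold probability cutoff.
#' @return a `stage_report`: stage name, labels, split, fitted models, per-
#'   algorithm test characteristics, the selected initial model, and the
#'   consumed (reviewed) ids.
#' @export
run_development_stage <- function(cohort, lexicon = default_lexicon(),
                                  rule = adjudication_rule(),
                                  review_budget = 980L,
                                  config = stage_training_config(),
                                  test_fraction = 0.3, threshold = 0.5) {
  stopifnot(review_budget > 0)
  screen <- screen_cohort(cohort, lexicon)
  ranked <- rank_screened(screen)
  if (length(ranked) == 0L) {
    stop("development stage: screening flagged no records; nothing to review")
  }
  labels <- review_batch(ranked, cohort, rule, review_budget)
  if (length(unique(labels$label)) < 2L) {
    stop("development stage: reviewed charts contain a single class; ",
         "increase review_budget")
  }
  features <- build_feature_matrix(cohort, lexicon, ids = labels$patient_id)
  split <- split_cohort(labels, test_fraction, stratified = TRUE,
                        seed = child_seed(config$seed, "development-split"))
  sel <- train_and_select(features, labels, split, config, threshold)
  structure(
    list(stage = "development", labels = labels, screen = screen,
         split = split, models = sel$models,
         characteristics = sel$characteristics,
         best_algorithm = sel$best_algorithm,
         model = sel$models[[sel$best_algorithm]],
         n_cases = sum(labels$label == "PAH"),
         n_noncases = sum(labels$label == "not_PAH"),
         consumed_ids = labels$patient_id),
    class = "stage_report"
  )
}

#' Refinement stage: model-guided case finding
#'
#' Deploys the Initial Algorithm on the flagged records that were not
#' reviewed during development and sends only the predicted positives to
#' adjudication (predicted negatives are never reviewed, exactly as in a
#' manual-review budget; the resulting verification bias is a property of
#' the procedure, not corrected here). Both confirmed cases and refuted
#' non-cases enter the final cohort.
#'
#' @param initial_model the development-stage `pah_model`.
#' @param cohort an `emr_cohort`.
#' @param remaining_ids flagged ids not reviewed during development.
#' @param development_ids ids consumed by the development stage; any overlap
#'   with `remaining_ids` is an error.
#' @param lexicon,rule,threshold as elsewhere.
#' @return data.table (`patient_id`, `label`) for the adjudicated predicted
#'   positives (possibly empty).
#' @export
run_refinement_stage <- function(initial_model, cohort, remaining_ids,
                                 development_ids,
                                 lexicon = default_lexicon(),
                                 rule = adjudication_rule(),
                                 threshold = 0.5) {
  overlap <- intersect(remaining_ids, development_ids)
  if (length(overlap)) {
    stop("refinement candidates overlap the development cohort (e.g. ",
         overlap[1L], ")")
  }
  if (length(remaining_ids) == 0L) {
    return(data.table(patient_id = character(), label = character()))
  }
  features <- build_feature_matrix(cohort, lexicon, ids = remaining_ids)
  pred <- predict(initial_model, features, threshold = threshold)
  positives <- pred$patient_id[pred$label == "PAH"]
  if (length(positives) == 0L) {
    return(data.table(patient_id = character(), label = character()))
  }
  adjudicate_ids(cohort, positives, rule)
}

#' Assemble the final labeled cohort
#'
#' Union of the development and refinement label sets, dropping
#' development-stage patients younger than the rule's adult age minimum.
#' Conflicting duplicate labels are an error.
#'
#' @param development_labels,refinement_labels data.frames
#'   (`patient_id`, `label`).
#' @param cohort an `emr_cohort` (for ages).
#' @param rule an `adjudication_rule` (for `adult_age_min`).
#' @return data.table (`patient_id`, `label`, `stage`).
#' @export
build_final_cohort <- function(development_labels, refinement_labels, cohort,
                               rule = adjudication_rule()) {
  dev <- as.data.table(development_labels)[, .(patient_id, label)]
  ref <- as.data.table(refinement_labels)[, .(patient_id, label)]
  dup <- intersect(dev$patient_id, ref$patient_id)
  if (length(dup)) {
    d <- dev[patient_id %in% dup]; r <- ref[patient_id %in% dup]
    conflict <- merge(d, r, by = "patient_id")[label.x != label.y]
    if (nrow(conflict)) {
      stop("conflicting labels for patient ", conflict$patient_id[1L])
    }
    ref <- ref[!patient_id %in% dup]
  }
  ages <- cohort$patients[, .(patient_id, age_years)]
  dev <- merge(dev, ages, by = "patient_id")
  dev <- dev[age_years >= rule$adult_age_min, .(patient_id, label)]
  dev[, stage := "development"]
  ref[, stage := "refinement"]
  out <- rbindlist(list(dev, ref))
  setorder(out, patient_id)
  out
}

#' Final stage: fresh training on the combined cohort
#'
#' Performs a stratified 80/20 split of the final labeled cohort and trains
#' all three algorithm families from scratch (no fitted state is inherited
#' from the development stage; all parameters are re-initialized and re-tuned
#' on the final training set). Test characteristics are computed once on the
#' untouched test set. The random forest is designated final unless
#' overridden.
#'
#' @param cohort an `emr_cohort`.
#' @param final_labels labeled cohort from [build_final_cohort()].
#' @param lexicon a `pah_lexicon`.
#' @param config a [stage_training_config()].
#' @param test_fraction held-out fraction (default 0.2).
#' @param threshold probability cutoff.
#' @param final_algorithm which family to designate final (default
#'   `random_forest`).
#' @return a `stage_report` with the designated final model.
#' @export
run_final_stage <- function(cohort, final_labels,
                            lexicon = default_lexicon(),
                            config = stage_training_config(),
                            test_fraction = 0.2, threshold = 0.5,
                            final_algorithm = "random_forest") {
  labels <- as.data.table(final_labels)[, .(patient_id, label)]
  if (length(unique(labels$label)) < 2L) {
    stop("final stage: both classes must be present")
  }
  features <- build_feature_matrix(cohort, lexicon, ids = labels$patient_id)
  split <- split_cohort(labels, test_fraction, stratified = TRUE,
                        seed = child_seed(config$seed, "final-split"))
  sel <- train_and_select(features, labels, split, config, threshold)
  structure(
    list(stage = "final", labels = labels, split = split,
         models = sel$models, characteristics = sel$characteristics,
         best_algorithm = sel$best_algorithm,
         model = sel$models[[final_algorithm]],
         final_algorithm = final_algorithm,
         n_cases = sum(labels$label == "PAH"),
         n_noncases = sum(labels$label == "not_PAH"),
         consumed_ids = labels$patient_id),
    class = "stage_report"
  )
}

#' @export
print.stage_report <- function(x, ...) {
  cat("<stage_report> ", x$stage, ": ", x$n_cases, " cases / ",
      x$n_noncases, " non-cases; train ", length(x$split$train_ids),
      ", test ", length(x$split$test_ids), "\n", sep = "")
  for (alg in names(x$characteristics)) {
    tc <- x$characteristics[[alg]]
    cat(sprintf("  %-13s AUC %.3f Se %.3f Sp %.3f\n", alg, tc$auc,
                tc$sensitivity, tc$specificity))
  }
  invisible(x)
}

#' Split-cohort internal validation (deployment)
#'
#' Deploys the final model on every patient not consumed by the training
#' stages: all remaining patients are screened and featurized (unflagged
#' patients contribute all-zero rows), scored, and the predicted positives
#' are aggregated into a registry-style summary via
#' [characteristics_table()]. No adjudication occurs — this simulates
#' application to an administrative claims database where no chart review is
#' possible.
#'
#' @param final_model a `pah_model`.
#' @param cohort an `emr_cohort`.
#' @param consumed_ids ids used in any training stage (excluded here).
#' @param lexicon a `pah_lexicon`.
#' @param threshold probability cutoff.
#' @return list: `predicted_ids`, `scores` (full prediction table),
#'   `summary` (a `case_summary`).
#' @export
internal_validation <- function(final_model, cohort, consumed_ids,
                                lexicon = default_lexicon(),
                                threshold = 0.5) {
  stopifnot(inherits(cohort, "emr_cohort"))
  deploy_ids <- setdiff(cohort$patients$patient_id, consumed_ids)
  if (length(deploy_ids) == 0L) {
    return(list(predicted_ids = character(),
                scores = data.frame(patient_id = character(),
                                    score = numeric(), label = character()),
                summary = characteristics_table(character(), cohort, lexicon)))
  }
  features <- build_feature_matrix(cohort, lexicon, ids = deploy_ids)
  pred <- predict(final_model, features, threshold = threshold)
  positives <- pred$patient_id[pred$label == "PAH"]
  list(predicted_ids = positives, scores = pred,
       summary = characteristics_table(positives, cohort, lexicon))
}
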