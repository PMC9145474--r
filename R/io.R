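#' Write / read an EMR cohort as delimited tables
#'
#' The interchange format is four UTF-8 CSV files with header rows and
#' ISO-8601 dates: `events.csv` (patient_id, date, vocabulary, code),
#' `patients.csv` (patient_id, age_years, sex, record_start, record_end),
#' `hemodynamics.csv` (patient_id, mRA, mPAP, PCWP, CO, CI, PVR), and — for
#' synthetic cohorts — `truth.csv` (patient_id, truth_label, stratum), kept
#' in a separate file so pipeline stages cannot accidentally read it.
#'
#' @param cohort an `emr_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "emr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("patients.csv", "events.csv",
                            "hemodynamics.csv", "truth.csv"))
  utils::write.csv(cohort$patients, paths[1L], row.names = FALSE)
  utils::write.csv(cohort$events, paths[2L], row.names = FALSE)
  written <- paths[1:2]
  if (!is.null(cohort$hemodynamics)) {
    utils::write.csv(cohort$hemodynamics, paths[3L], row.names = FALSE)
    written <- c(written, paths[3L])
  }
  if (!is.null(cohort$truth)) {
    utils::write.csv(cohort$truth, paths[4L], row.names = FALSE)
    written <- c(written, paths[4L])
  }
  invisible(written)
}

parse_iso_dates <- function(x, what) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & x != "")
  if (length(bad)) {
    stop("unparseable ", what, " date '", x[bad[1L]], "' at row ", bad[1L])
  }
  d
}

#' @rdname write_cohort
#' @param patients,events,hemodynamics,truth file paths; `hemodynamics` and
#'   `truth` may be `NULL`/absent. A directory written by [write_cohort()]
#'   can be passed as `dir` instead.
#' @export
load_tables <- function(patients = NULL, events = NULL, hemodynamics = NULL,
                        truth = NULL, dir = NULL) {
  if (!is.null(dir)) {
    patients <- file.path(dir, "patients.csv")
    events <- file.path(dir, "events.csv")
    h <- file.path(dir, "hemodynamics.csv")
    t <- file.path(dir, "truth.csv")
    hemodynamics <- if (file.exists(h)) h
    truth <- if (file.exists(t)) t
  }
  for (p in c(patients, events)) {
    if (!file.exists(p)) stop("input table not found: ", p)
  }
  pt <- as.data.table(utils::read.csv(patients, colClasses = "character"))
  pt[, age_years := as.numeric(age_years)]
  pt[, record_start := parse_iso_dates(record_start, "record_start")]
  pt[, record_end := parse_iso_dates(record_end, "record_end")]
  ev <- as.data.table(utils::read.csv(events, colClasses = "character"))
  if (nrow(ev) > 0L) {
    ev[, date := parse_iso_dates(date, "event")]
  } else {
    ev <- data.table(patient_id = character(), date = as.Date(character()),
                     vocabulary = character(), code = character())
  }
  hm <- NULL
  if (!is.null(hemodynamics) && file.exists(hemodynamics)) {
    hm <- as.data.table(utils::read.csv(hemodynamics))
    hm[, patient_id := as.character(patient_id)]
    if (nrow(hm) == 0L) hm <- NULL
  }
  tr <- NULL
  if (!is.null(truth) && file.exists(truth)) {
    tr <- as.data.table(utils::read.csv(truth, colClasses = "character"))
    if (nrow(tr) == 0L) tr <- NULL
  }
  emr_cohort(pt, ev, hm, tr, validate = TRUE)
}

#' End-to-end run configuration
#'
#' Bundles everything [run_all()] needs: either a simulation config (the
#' cohort is generated) or input table paths (the cohort is loaded), the
#' lexicon, adjudication rule, review budget, stage training settings,
#' thresholds and the master seed from which each stage derives its own
#' deterministic sub-seed.
#'
#' @param simulation a [simulation_config()], or `NULL` when loading tables.
#' @param input_dir directory of CSV tables (used when `simulation` is NULL).
#' @param lexicon a `pah_lexicon`.
#' @param rule an `adjudication_rule`.
#' @param review_budget development-stage chart budget.
#' @param training a [stage_training_config()].
#' @param threshold probability cutoff used throughout.
#' @param test_fraction_development,test_fraction_final split fractions.
#' @param final_algorithm family designated final.
#' @param out_dir optional directory for stage-report JSON artifacts.
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = simulation_config(), input_dir = NULL,
                       lexicon = default_lexicon(),
                       rule = adjudication_rule(), review_budget = 980L,
                       training = stage_training_config(), threshold = 0.5,
                       test_fraction_development = 0.3,
                       test_fraction_final = 0.2,
                       final_algorithm = "random_forest",
                       out_dir = NULL, seed = 1L) {
  if (is.null(simulation) && is.null(input_dir)) {
    stop("run_config: provide either a simulation config or an input_dir")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("run_config: input_dir does not exist: ", input_dir)
  }
  structure(
    list(simulation = simulation, input_dir = input_dir, lexicon = lexicon,
         rule = rule, review_budget = as.integer(review_budget),
         training = training, threshold = threshold,
         test_fraction_development = test_fraction_development,
         test_fraction_final = test_fraction_final,
         final_algorithm = final_algorithm, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

stage_report_json <- function(report) {
  tc_list <- lapply(report$characteristics, function(tc) {
    tc[c("n", "tp", "fp", "fn", "tn", "auc", "sensitivity", "specificity",
         "ppv", "npv")]
  })
  list(stage = report$stage, n_cases = report$n_cases,
       n_noncases = report$n_noncases,
       n_train = length(report$split$train_ids),
       n_test = length(report$split$test_ids),
       best_algorithm = report$best_algorithm,
       test_characteristics = tc_list)
}

#' Run the whole multi-stage pipeline
#'
#' Executes simulate (or load) -> screen -> develop -> refine -> finalize ->
#' deploy, mirroring the study funnel: a screening tool narrows the
#' population, a budgeted chart review builds the development cohort, the
#' Initial Algorithm proposes further cases for review, the final cohort is
#' retrained from scratch, and the final model is deployed on every patient
#' never used for training. Re-running with the same config reproduces every
#' artifact.
#'
#' @param config a [run_config()].
#' @param verbose print the stage funnel counts?
#' @return list with the cohort, screening table, `development` and `final`
#'   stage reports, refinement labels, final labeled cohort, and the
#'   `validation` deployment summary.
#' @export
run_all <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)

  cohort <- if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- child_seed(config$seed, "simulate")
    simulate_cohort(sim)
  } else {
    load_tables(dir = config$input_dir)
  }
  say("population: ", nrow(cohort$patients), " patients, ",
      nrow(cohort$events), " events")

  training <- config$training
  training$seed <- child_seed(config$seed, "train")

  screen <- screen_cohort(cohort, config$lexicon)
  say("screening: ", sum(screen$flagged), " flagged of ", nrow(screen))

  dev <- run_development_stage(
    cohort, config$lexicon, config$rule, config$review_budget, training,
    test_fraction = config$test_fraction_development,
    threshold = config$threshold)
  say("development: reviewed ", nrow(dev$labels), " charts -> ",
      dev$n_cases, " PAH / ", dev$n_noncases, " not PAH; best ",
      dev$best_algorithm)

  ranked <- rank_screened(screen)
  remaining <- setdiff(ranked, dev$consumed_ids)
  refinement <- run_refinement_stage(
    dev$model, cohort, remaining, dev$consumed_ids, config$lexicon,
    config$rule, config$threshold)
  say("refinement: ", nrow(refinement), " predicted cases reviewed -> ",
      sum(refinement$label == "PAH"), " confirmed")

  final_labels <- build_final_cohort(dev$labels, refinement, cohort,
                                     config$rule)
  final <- run_final_stage(
    cohort, final_labels, config$lexicon, training,
    test_fraction = config$test_fraction_final,
    threshold = config$threshold,
    final_algorithm = config$final_algorithm)
  say("final: ", final$n_cases, " cases / ", final$n_noncases,
      " non-cases; test AUC ",
      sprintf("%.3f", final$characteristics[[config$final_algorithm]]$auc))

  consumed <- union(dev$consumed_ids, final$consumed_ids)
  validation <- internal_validation(final$model, cohort, consumed,
                                    config$lexicon, config$threshold)
  say("deployment: ", length(validation$predicted_ids),
      " predicted cases among ",
      nrow(cohort$patients) - length(consumed), " unreviewed patients")

  result <- list(cohort = cohort, screen = screen, development = dev,
                 refinement = refinement, final_labels = final_labels,
                 final = final, validation = validation,
                 consumed_ids = consumed, seed = config$seed)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_json <- function(x, f) {
      jsonlite::write_json(x, file.path(config$out_dir, f),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    write_json(stage_report_json(dev), "development.json")
    write_json(list(stage = "refinement", n_reviewed = nrow(refinement),
                    n_confirmed = sum(refinement$label == "PAH")),
               "refinement.json")
    write_json(stage_report_json(final), "final.json")
    s <- validation$summary
    write_json(list(stage = "deployment", n_predicted = s$n,
                    age_mean = s$age_mean, age_sd = s$age_sd,
                    pct_female = s$pct_female, pct_ctd = s$pct_ctd,
                    pct_chd = s$pct_chd,
                    med_class_pct = as.list(s$med_class_pct),
                    n_hemodynamics = s$n_hemodynamics,
                    hemodynamics = s$hemodynamics),
               "deployment.json")
  }
  invisible(result)
}
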