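# Independent oracles and shared fixtures. Every oracle here is a naive,
# brute-force implementation kept deliberately separate from the package's
# production code paths.

# O(n^2) pair-counting AUC: ties contribute 1/2
oracle_auc_paircount <- function(scores, truth, positive = "PAH") {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# naive feature scan: for each variable walk all events, min/max dates
oracle_features_naive <- function(record, lexicon) {
  vars <- lexicon_variables(lexicon)
  mt <- as.data.frame(pahphen:::lexicon_match_table(lexicon))
  ev <- as.data.frame(record$events)
  voc <- ifelse(ev$vocabulary %in% c("ICD9", "ICD10"), "ICD", ev$vocabulary)
  out <- numeric(0)
  for (v in vars) {
    keys <- mt[mt$variable == v, ]
    hit <- rep(FALSE, nrow(ev))
    for (i in seq_len(nrow(keys))) {
      hit <- hit | (voc == keys$vocabulary[i] &
                      tolower(ev$code) == keys$code_lower[i])
    }
    if (!any(hit)) {
      s <- 0; p <- 0; d <- 0
    } else {
      dates <- ev$date[hit]
      s <- sum(hit)
      p <- as.numeric(max(dates) - min(dates))
      tail_days <- as.numeric(record$record_end - min(dates))
      d <- if (tail_days > 0) p / tail_days else 0
    }
    out <- c(out, s, p, d)
  }
  names(out) <- as.vector(t(outer(vars,
                                  c("strength", "persistence", "durability"),
                                  paste, sep = "__")))
  out
}

# brute-force Monte-Carlo means/sds of the constrained (truncated)
# hemodynamic distribution for one stratum
oracle_truncated_hemo <- function(params, rule = adjudication_rule(),
                                  constraint = c("wsph", "not_wsph",
                                                 "postcapillary"),
                                  n = 2e5, seed = 999) {
  constraint <- match.arg(constraint)
  set.seed(seed)
  mRA <- rnorm(n, params$mRA[1], params$mRA[2])
  mPAP <- rnorm(n, params$mPAP[1], params$mPAP[2])
  PCWP <- rnorm(n, params$PCWP[1], params$PCWP[2])
  CO <- rnorm(n, params$CO[1], params$CO[2])
  ok <- mRA >= 0 & mPAP >= 0 & PCWP >= 0 & CO >= 0.5
  PVR <- (mPAP - PCWP) / CO
  wsph <- mPAP >= rule$mpap_min & PVR >= rule$pvr_min & PCWP <= rule$pcwp_max
  keep <- ok & switch(constraint,
                      wsph = wsph,
                      not_wsph = !wsph,
                      postcapillary = PCWP > rule$pcwp_max)
  list(
    mean = c(mRA = mean(mRA[keep]), mPAP = mean(mPAP[keep]),
             PCWP = mean(PCWP[keep]), CO = mean(CO[keep]),
             PVR = mean(PVR[keep])),
    sd = c(mRA = sd(mRA[keep]), mPAP = sd(mPAP[keep]),
           PCWP = sd(PCWP[keep]), CO = sd(CO[keep]), PVR = sd(PVR[keep]))
  )
}

# scaled-down stage training settings used throughout the tests (package
# defaults follow the full tenfold x 3 / 30-iteration procedure)
small_training_config <- function(seed = 1L, cv_folds = 5L) {
  stage_training_config(
    cv_folds = cv_folds, cv_repeats = 1L, opt_init = 4L, opt_iterations = 4L,
    search_spaces = list(
      random_forest = list(
        num_trees = list(lower = 100, upper = 400, integer = TRUE),
        mtry_frac = list(lower = 0.05, upper = 1),
        min_node = list(lower = 1, upper = 20, integer = TRUE)),
      xgboost = list(
        eta = list(lower = 0.05, upper = 0.3),
        max_depth = list(lower = 2, upper = 6, integer = TRUE),
        nrounds = list(lower = 30, upper = 150, integer = TRUE),
        subsample = list(lower = 0.5, upper = 1)),
      elastic_net = list(
        alpha = list(lower = 0, upper = 1),
        lambda = list(lower = 1e-4, upper = 10, log = TRUE))),
    seed = seed)
}

small_model_config <- function(algorithm, seed = 1L, cv_folds = 3L,
                               opt_init = 3L, opt_iterations = 2L) {
  training_config(
    algorithm = algorithm, cv_folds = cv_folds, cv_repeats = 1L,
    opt_init = opt_init, opt_iterations = opt_iterations,
    search_space = small_training_config(seed)$search_spaces[[algorithm]],
    seed = seed)
}

# quick record builder
make_record <- function(id = "R1", span = 365, events = NULL,
                        start = as.Date("2010-01-01"), hemodynamics = NULL,
                        age = 50, sex = "female") {
  patient_record(id, age, sex, start, start + span, events = events,
                 hemodynamics = hemodynamics)
}

make_events <- function(start, days, vocabulary, code) {
  data.frame(date = as.Date(start) + days,
             vocabulary = rep_len(vocabulary, length(days)),
             code = rep_len(code, length(days)))
}

# a small hand-built labeled cohort with a clean separable signal: cases
# carry persistent medication + ICD + CPT mentions, controls isolated codes
make_separable_cohort <- function(n_cases = 20, n_controls = 30, span = 1000,
                                  seed = 1) {
  set.seed(seed)
  start <- as.Date("2010-01-01")
  recs <- list()
  for (i in seq_len(n_cases)) {
    days <- sort(sample(0:span, 12))
    ev <- rbind(
      make_events(start, days, "MED", "Flolan"),
      make_events(start, sample(0:span, 4), "ICD10", "I27.0"),
      make_events(start, sample(0:span, 1), "CPT", "93501"))
    hemo <- list(mRA = 10, mPAP = 50, PCWP = 10, CO = 4,
                 CI = 4 / 1.9, PVR = 10)
    recs[[length(recs) + 1L]] <- patient_record(
      sprintf("C%03d", i), 50, "female", start, start + span,
      events = ev, hemodynamics = hemo, truth_label = "PAH",
      stratum = "true_pah")
  }
  for (i in seq_len(n_controls)) {
    ev <- make_events(start, sample(0:span, 1), "MED", "Revatio")
    recs[[length(recs) + 1L]] <- patient_record(
      sprintf("N%03d", i), 60, "male", start, start + span,
      events = ev, truth_label = "not_PAH", stratum = "offlabel_med_user")
  }
  pahphen:::records_to_cohort(recs)
}
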