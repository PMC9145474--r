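#' Configuration for the synthetic EMR generator
#'
#' Builds the parameter set for [simulate_cohort()]. The generator emulates a
#' de-identified hospital EMR in which a rare pulmonary arterial hypertension
#' (PAH) subpopulation carries persistent PAH-medication mentions, right
#' heart catheterization (RHC) CPT codes and pulmonary-hypertension ICD
#' codes, against confounder strata that defeat naive rule-based screening:
#'
#' * `true_pah` — pre-capillary hemodynamics (WSPH-consistent), persistent
#'   medication use spanning most of the record, PH ICD codes and RHC CPT
#'   codes;
#' * `postcapillary_ph` — PH codes and RHC (wedge pressure > 15 mmHg), and
#'   occasionally a brief PDE5-inhibitor exposure;
#' * `offlabel_med_user` — isolated PDE5-inhibitor mentions with no PH ICD
#'   code and no RHC;
#' * `code_only` — a few PH ICD mentions, nothing else;
#' * `background` — none of the screened variables.
#'
#' Hemodynamic defaults follow the aggregate values reported for
#' algorithm-identified PAH cases (mPAP 49.8 +/- 13.6 mmHg, PCWP 11.3 +/- 6.1
#' mmHg, mRA 10.1 +/- 6.0 mmHg, CO 4.8 +/- 1.7 L/min); draws are
#' rejection-sampled from those normals until the stratum's constraint holds,
#' so the latent truth label is exactly consistent with the WSPH rule of
#' [adjudicate()].
#'
#' @param n_patients number of patients to simulate.
#' @param pah_prevalence fraction of the population in the `true_pah` stratum.
#' @param stratum_weights named fractions for the four non-PAH strata; must
#'   sum with `pah_prevalence` to 1.
#' @param record_span_days list(mean, sd, min) for the record-span draw (days).
#' @param stratum_profiles per-stratum mention-planting profiles; see
#'   [default_stratum_profiles()].
#' @param hemodynamic_params per-stratum list of c(mean, sd) for mRA, mPAP,
#'   PCWP, CO; strata other than `true_pah`/`postcapillary_ph` use `other`.
#' @param rhc_coverage named per-stratum fraction receiving a hemodynamics row.
#' @param age_params list of c(mean, sd) for `true_pah` and `other`.
#' @param female_fraction named fractions for `true_pah` and `other`.
#' @param comorbidity_rates list with `ctd` and `chd`, each c(true_pah, other).
#' @param noise_rate_per_year rate of non-lexicon background events.
#' @param bsa_m2 body surface area constant used to derive cardiac index.
#' @param lexicon the `pah_lexicon` whose codes are planted.
#' @param seed integer RNG seed; equal (config, seed) gives identical cohorts.
#' @return a `sim_config` object.
#' @export
simulation_config <- function(
    n_patients = 20000,
    pah_prevalence = 0.01,
    stratum_weights = c(postcapillary_ph = 0.05, offlabel_med_user = 0.03,
                        code_only = 0.03, background = 0.88),
    record_span_days = list(mean = 2920, sd = 1460, min = 180),
    stratum_profiles = default_stratum_profiles(),
    hemodynamic_params = list(
      true_pah = list(mRA = c(10.1, 6.0), mPAP = c(49.8, 13.6),
                      PCWP = c(11.3, 6.1), CO = c(4.8, 1.7)),
      postcapillary_ph = list(mRA = c(12, 5), mPAP = c(35, 8),
                              PCWP = c(22, 5), CO = c(5.0, 1.5)),
      other = list(mRA = c(6, 3), mPAP = c(18, 5),
                   PCWP = c(10, 4), CO = c(5.5, 1.2))
    ),
    rhc_coverage = c(true_pah = 1.0, postcapillary_ph = 0.9,
                     offlabel_med_user = 0.1, code_only = 0.3,
                     background = 0.02),
    age_params = list(true_pah = c(52, 14), other = c(52, 21)),
    female_fraction = c(true_pah = 0.721, other = 0.542),
    comorbidity_rates = list(ctd = c(true_pah = 0.332, other = 0.02),
                             chd = c(true_pah = 0.192, other = 0.009)),
    noise_rate_per_year = 2,
    bsa_m2 = 1.9,
    lexicon = default_lexicon(),
    seed = 1L) {
  cfg <- structure(
    list(n_patients = n_patients, pah_prevalence = pah_prevalence,
         stratum_weights = stratum_weights,
         record_span_days = record_span_days,
         stratum_profiles = stratum_profiles,
         hemodynamic_params = hemodynamic_params,
         rhc_coverage = rhc_coverage, age_params = age_params,
         female_fraction = female_fraction,
         comorbidity_rates = comorbidity_rates,
         noise_rate_per_year = noise_rate_per_year, bsa_m2 = bsa_m2,
         lexicon = lexicon, seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

sim_strata <- c("true_pah", "postcapillary_ph", "offlabel_med_user",
                "code_only", "background")

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("invalid simulation config: field '", field, "' ", msg)
  }
  if (length(cfg$n_patients) != 1L || is.na(cfg$n_patients) ||
      cfg$n_patients < 0 || cfg$n_patients != round(cfg$n_patients)) {
    fail("n_patients", "must be a non-negative integer")
  }
  if (cfg$pah_prevalence < 0 || cfg$pah_prevalence >= 1) {
    fail("pah_prevalence", "must lie in [0, 1)")
  }
  w <- cfg$stratum_weights
  if (!all(setdiff(sim_strata, "true_pah") %in% names(w))) {
    fail("stratum_weights", "must name postcapillary_ph, offlabel_med_user, code_only, background")
  }
  if (any(w < 0)) fail("stratum_weights", "must be non-negative")
  if (abs(sum(w) + cfg$pah_prevalence - 1) > 1e-8) {
    fail("stratum_weights", "must sum with pah_prevalence to 1")
  }
  sp <- cfg$record_span_days
  if (is.null(sp$min) || sp$min < 1) fail("record_span_days", "min must be >= 1 day")
  if (is.null(sp$sd) || sp$sd < 0) fail("record_span_days", "sd must be non-negative")
  if (any(cfg$rhc_coverage < 0 | cfg$rhc_coverage > 1)) {
    fail("rhc_coverage", "entries must lie in [0, 1]")
  }
  for (s in names(cfg$hemodynamic_params)) {
    for (v in names(cfg$hemodynamic_params[[s]])) {
      if (cfg$hemodynamic_params[[s]][[v]][2L] < 0) {
        fail("hemodynamic_params", paste0("(", s, ", ", v, ") sd must be non-negative"))
      }
    }
  }
  if (cfg$noise_rate_per_year < 0) fail("noise_rate_per_year", "must be non-negative")
  if (!inherits(cfg$lexicon, "pah_lexicon")) fail("lexicon", "must be a pah_lexicon")
  invisible(cfg)
}

#' Default per-stratum mention-planting profiles
#'
#' A profile says, for one generating stratum, how the screened variables are
#' written into a record: which medication classes the patient is exposed to
#' (probability per class), how many mentions each chosen drug gets and what
#' fraction of the record they span, and likewise for PH ICD codes and RHC
#' CPT codes. `med_span` is the first-to-last mention distance as a fraction
#' of the record, so `true_pah` patients show sustained therapy (high
#' persistence/durability) while off-label users show isolated mentions.
#' `span_days` optionally overrides the global record-span distribution for
#' one stratum, and `ensure_med = TRUE` guarantees at least one medication
#' class (used for `true_pah`, whose patients are treated by definition).
#'
#' @return named list of profiles, one per stratum.
#' @export
default_stratum_profiles <- function() {
  list(
    true_pah = list(
      med_class_probs = c(prostanoid = 0.63, pde5 = 0.84, era = 0.70,
                          gc_stim = 0.015),
      ensure_med = TRUE,  # treated PAH: at least one PAH-specific drug
      med_mentions = c(8L, 30L), med_span = c(0.50, 0.90),
      icd_prob = 1.0, icd_mentions = c(3L, 10L), icd_span = c(0.40, 0.90),
      cpt_prob = 1.0, cpt_mentions = c(1L, 3L),
      span_days = NULL
    ),
    postcapillary_ph = list(
      med_class_probs = c(pde5 = 0.20),
      med_mentions = c(1L, 3L), med_span = c(0.00, 0.05),
      icd_prob = 0.9, icd_mentions = c(2L, 6L), icd_span = c(0.10, 0.50),
      cpt_prob = 0.8, cpt_mentions = c(1L, 2L),
      span_days = NULL
    ),
    offlabel_med_user = list(
      med_class_probs = c(pde5 = 1.0),
      med_mentions = c(1L, 3L), med_span = c(0.00, 0.05),
      icd_prob = 0.0, icd_mentions = c(0L, 0L), icd_span = c(0, 0),
      cpt_prob = 0.0, cpt_mentions = c(0L, 0L),
      span_days = NULL
    ),
    code_only = list(
      med_class_probs = numeric(),
      med_mentions = c(0L, 0L), med_span = c(0, 0),
      icd_prob = 1.0, icd_mentions = c(1L, 3L), icd_span = c(0.00, 0.10),
      cpt_prob = 0.0, cpt_mentions = c(0L, 0L),
      span_days = NULL
    ),
    background = list(
      med_class_probs = numeric(),
      med_mentions = c(0L, 0L), med_span = c(0, 0),
      icd_prob = 0.0, icd_mentions = c(0L, 0L), icd_span = c(0, 0),
      cpt_prob = 0.0, cpt_mentions = c(0L, 0L),
      span_days = NULL
    )
  )
}

# non-lexicon codes used as background noise
noise_code_pool <- data.table::data.table(
  vocabulary = c("ICD10", "ICD10", "ICD10", "ICD10", "ICD10", "ICD10",
                 "ICD9", "ICD9", "CPT", "CPT", "MED", "MED", "MED"),
  code = c("I10", "E11.9", "J44.9", "K21.9", "M54.5", "F41.9",
           "401.9", "272.4", "99213", "93000",
           "furosemide", "metoprolol", "lisinopril")
)

# dates (integer day offsets in [0, span]) for n mentions covering
# span_frac of the record, starting at a uniform offset
mention_days <- function(n, span_days, frac_range) {
  if (n <= 0L) return(integer())
  frac <- runif(1L, frac_range[1L], frac_range[2L])
  start <- runif(1L, 0, max(0, 1 - frac)) * span_days
  width <- frac * span_days
  if (n == 1L) return(as.integer(round(start + runif(1L) * width)))
  inner <- if (n > 2L) sort(runif(n - 2L)) else numeric()
  pmin(span_days, pmax(0L, as.integer(round(start + width * c(0, inner, 1)))))
}

rint <- function(range) {
  if (range[2L] <= range[1L]) return(as.integer(range[1L]))
  sample(seq.int(range[1L], range[2L]), 1L)
}

# core event planter: given a record span in days, a stratum profile and the
# lexicon, emit a table of (day, vocabulary, code)
plant_events_core <- function(span_days, profile, lexicon, comorbid_ctd,
                              comorbid_chd, noise_rate_per_year) {
  classes <- default_med_classes()
  out <- vector("list", 8L)
  k <- 0L
  # medications: one drug per exposed class, mentions under brand or generic
  exposed <- names(profile$med_class_probs)[
    runif(length(profile$med_class_probs)) <= profile$med_class_probs]
  if (isTRUE(profile$ensure_med) && length(exposed) == 0L &&
      length(profile$med_class_probs) > 0L) {
    exposed <- names(which.max(profile$med_class_probs))
  }
  for (cl in exposed) {
    generic <- sample(classes[[cl]], 1L)
    alias <- sample(lexicon$medications[[generic]], 1L)
    n <- rint(profile$med_mentions)
    if (n > 0L) {
      k <- k + 1L
      out[[k]] <- data.table(
        day = mention_days(n, span_days, profile$med_span),
        vocabulary = "MED", code = alias)
    }
  }
  # pulmonary-hypertension ICD codes
  if (profile$icd_prob > 0 && runif(1L) <= profile$icd_prob) {
    code <- sample(c("I27.0", "416.0", "I27.20"), 1L, prob = c(0.65, 0.25, 0.10))
    n <- rint(profile$icd_mentions)
    if (n > 0L) {
      k <- k + 1L
      out[[k]] <- data.table(
        day = mention_days(n, span_days, profile$icd_span),
        vocabulary = if (code == "416.0") "ICD9" else "ICD10", code = code)
    }
  }
  # right-heart-catheterization CPT codes, anywhere in the record
  if (profile$cpt_prob > 0 && runif(1L) <= profile$cpt_prob) {
    n <- rint(profile$cpt_mentions)
    if (n > 0L) {
      ncpt <- length(lexicon$cpt_codes)
      cpt_prob <- if (ncpt == 1L) 1 else
        c(0.5, rep(0.5 / (ncpt - 1L), ncpt - 1L))  # favor the classic 93501
      codes <- sample(lexicon$cpt_codes, n, replace = TRUE, prob = cpt_prob)
      k <- k + 1L
      out[[k]] <- data.table(
        day = as.integer(round(runif(n) * span_days)),
        vocabulary = "CPT", code = codes)
    }
  }
  # comorbidity diagnoses (CTD / CHD)
  cmb <- default_comorbidity_codes()
  if (comorbid_ctd) {
    code <- sample(cmb$ctd, 1L)
    k <- k + 1L
    out[[k]] <- data.table(
      day = as.integer(round(runif(rint(c(1L, 3L))) * span_days)),
      vocabulary = if (grepl("^7", code)) "ICD9" else "ICD10", code = code)
  }
  if (comorbid_chd) {
    code <- sample(cmb$chd, 1L)
    k <- k + 1L
    out[[k]] <- data.table(
      day = as.integer(round(runif(rint(c(1L, 3L))) * span_days)),
      vocabulary = if (grepl("^7", code)) "ICD9" else "ICD10", code = code)
  }
  # background noise, none of it in the lexicon
  n_noise <- rpois(1L, noise_rate_per_year * span_days / 365.25)
  if (n_noise > 0L) {
    idx <- sample.int(nrow(noise_code_pool), n_noise, replace = TRUE)
    k <- k + 1L
    out[[k]] <- data.table(
      day = as.integer(round(runif(n_noise) * span_days)),
      vocabulary = noise_code_pool$vocabulary[idx],
      code = noise_code_pool$code[idx])
  }
  if (k == 0L) {
    return(data.table(day = integer(), vocabulary = character(),
                      code = character()))
  }
  rbindlist(out[seq_len(k)])
}

#' Plant a stratum's coded signal into one patient record
#'
#' Writes the mention pattern of the given generating stratum into an
#' (otherwise signal-free) record: `true_pah` receives sustained medication
#' mentions plus RHC CPT and PH ICD events; `offlabel_med_user` receives
#' isolated PDE5-inhibitor mentions and no PH ICD code; `code_only` receives
#' PH ICD mentions only; `background` receives none of the screened
#' variables.
#'
#' @param record a `patient_record` with a valid span.
#' @param stratum one of `true_pah`, `postcapillary_ph`, `offlabel_med_user`,
#'   `code_only`, `background`.
#' @param config a `sim_config`.
#' @return the record with planted events appended (sorted by date).
#' @export
plant_signal <- function(record, stratum, config = simulation_config()) {
  stopifnot(inherits(record, "patient_record"))
  if (!stratum %in% sim_strata || is.null(config$stratum_profiles[[stratum]])) {
    stop("unknown stratum: ", stratum)
  }
  span_days <- as.integer(record$record_end - record$record_start)
  ev <- plant_events_core(span_days, config$stratum_profiles[[stratum]],
                          config$lexicon,
                          comorbid_ctd = FALSE, comorbid_chd = FALSE,
                          noise_rate_per_year = 0)
  new_events <- data.table(date = record$record_start + ev$day,
                           vocabulary = ev$vocabulary, code = ev$code)
  record$events <- rbindlist(list(record$events, new_events))
  setorder(record$events, date, vocabulary, code)
  record$stratum <- stratum
  record
}

# rejection-sample n hemodynamic rows from stratum normals subject to a
# constraint keeping truth and the WSPH rule exactly consistent
sample_hemodynamics <- function(n, params, constraint, bsa_m2, rule) {
  if (n == 0L) {
    return(data.table(mRA = numeric(), mPAP = numeric(), PCWP = numeric(),
                      CO = numeric(), CI = numeric(), PVR = numeric()))
  }
  draw <- function(m) {
    mRA <- rnorm(m, params$mRA[1L], params$mRA[2L])
    mPAP <- rnorm(m, params$mPAP[1L], params$mPAP[2L])
    PCWP <- rnorm(m, params$PCWP[1L], params$PCWP[2L])
    CO <- rnorm(m, params$CO[1L], params$CO[2L])
    ok <- mRA >= 0 & mPAP >= 0 & PCWP >= 0 & CO >= 0.5
    PVR <- (mPAP - PCWP) / CO
    keep <- ok & constraint(mPAP, PCWP, PVR, rule)
    data.table(mRA = mRA, mPAP = mPAP, PCWP = PCWP, CO = CO)[keep]
  }
  acc <- draw(max(4L * n, 100L))
  tries <- 0L
  while (nrow(acc) < n) {
    tries <- tries + 1L
    if (tries > 200L) stop("hemodynamic rejection sampler failed to satisfy the stratum constraint; check hemodynamic_params")
    acc <- rbindlist(list(acc, draw(max(4L * n, 100L))))
  }
  acc <- acc[seq_len(n)]
  acc[, CI := CO / bsa_m2]
  acc[, PVR := (mPAP - PCWP) / CO]
  acc[]
}

hemo_constraints <- list(
  true_pah = function(mPAP, PCWP, PVR, rule) wsph_pass(mPAP, PCWP, PVR, rule),
  postcapillary_ph = function(mPAP, PCWP, PVR, rule) PCWP > rule$pcwp_max,
  other = function(mPAP, PCWP, PVR, rule) !wsph_pass(mPAP, PCWP, PVR, rule)
)

#' Simulate a synthetic EMR cohort
#'
#' Draws a population under a [simulation_config()]: stratum membership is a
#' multinomial draw (so the realized PAH count is binomial at
#' `pah_prevalence`), demographics and record spans come from the configured
#' distributions, each stratum's coded signal is planted by the profile
#' machinery of [plant_signal()], and hemodynamics are rejection-sampled so
#' that the latent `truth_label` equals the WSPH adjudication of the record.
#' Identical configs (including seed) yield byte-identical cohorts.
#'
#' @param config a `sim_config`.
#' @return an `emr_cohort` with the synthetic `truth` table attached.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_patients = 200, seed = 42))
#' cohort
simulate_cohort <- function(config = simulation_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_patients)
  if (n == 0L) {
    return(emr_cohort(
      patients = data.table(patient_id = character(), age_years = numeric(),
                            sex = character(),
                            record_start = as.Date(character()),
                            record_end = as.Date(character())),
      events = data.table(patient_id = character(),
                          date = as.Date(character()),
                          vocabulary = character(), code = character()),
      hemodynamics = NULL,
      truth = data.table(patient_id = character(), truth_label = character(),
                         stratum = character())
    ))
  }
  rule <- adjudication_rule()
  probs <- c(true_pah = config$pah_prevalence,
             config$stratum_weights[setdiff(sim_strata, "true_pah")])
  stratum <- sample(names(probs), n, replace = TRUE, prob = probs)
  ids <- sprintf("P%06d", seq_len(n))
  is_pah <- stratum == "true_pah"

  age_mean <- ifelse(is_pah, config$age_params$true_pah[1L],
                     config$age_params$other[1L])
  age_sd <- ifelse(is_pah, config$age_params$true_pah[2L],
                   config$age_params$other[2L])
  age <- pmax(1, rnorm(n, age_mean, age_sd))
  fem <- ifelse(is_pah, config$female_fraction[["true_pah"]],
                config$female_fraction[["other"]])
  sex <- ifelse(runif(n) < fem, "female", "male")

  # per-stratum record spans (a profile may override the global distribution)
  sp <- config$record_span_days
  span <- pmax(sp$min, round(rnorm(n, sp$mean, sp$sd)))
  for (s in sim_strata) {
    ov <- config$stratum_profiles[[s]]$span_days
    if (!is.null(ov)) {
      idx <- which(stratum == s)
      span[idx] <- pmax(ov$min, round(rnorm(length(idx), ov$mean, ov$sd)))
    }
  }
  start <- as.Date("2000-01-01") + as.integer(floor(runif(n, 0, 5478)))
  end <- start + span

  ctd <- runif(n) < ifelse(is_pah, config$comorbidity_rates$ctd[["true_pah"]],
                           config$comorbidity_rates$ctd[["other"]])
  chd <- runif(n) < ifelse(is_pah, config$comorbidity_rates$chd[["true_pah"]],
                           config$comorbidity_rates$chd[["other"]])

  # plant events patient by patient (profiles are light; rbindlist at the end)
  ev_list <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- plant_events_core(span[i], config$stratum_profiles[[stratum[i]]],
                            config$lexicon, ctd[i], chd[i],
                            config$noise_rate_per_year)
    if (nrow(ev) > 0L) {
      ev_list[[i]] <- data.table(patient_id = ids[i], day = ev$day,
                                 vocabulary = ev$vocabulary, code = ev$code)
    }
  }
  events <- rbindlist(ev_list[!vapply(ev_list, is.null, logical(1L))])
  if (nrow(events) > 0L) {
    events <- merge(events,
                    data.table(patient_id = ids, record_start = start),
                    by = "patient_id")
    events <- events[, .(patient_id, date = record_start + day,
                         vocabulary, code)]
    setorder(events, patient_id, date, vocabulary, code)
  } else {
    events <- data.table(patient_id = character(),
                         date = as.Date(character()),
                         vocabulary = character(), code = character())
  }

  # hemodynamics: coverage draw, then constrained sampling per stratum
  hemo_list <- list()
  for (s in sim_strata) {
    idx <- which(stratum == s)
    if (!length(idx)) next
    cov <- config$rhc_coverage[[s]] %||% 0
    take <- idx[runif(length(idx)) < cov]
    if (!length(take)) next
    params <- config$hemodynamic_params[[s]] %||% config$hemodynamic_params$other
    constraint <- hemo_constraints[[s]] %||% hemo_constraints$other
    h <- sample_hemodynamics(length(take), params, constraint,
                             config$bsa_m2, rule)
    hemo_list[[s]] <- data.table(patient_id = ids[take], h)
  }
  hemodynamics <- if (length(hemo_list)) {
    h <- rbindlist(hemo_list)
    setorder(h, patient_id)
    h
  }

  # truth = the WSPH rule applied to the hemodynamics (exact by construction)
  truth_label <- rep("not_PAH", n)
  if (!is.null(hemodynamics)) {
    pass <- hemodynamics[wsph_pass(mPAP, PCWP, PVR, rule), patient_id]
    truth_label[ids %in% pass] <- "PAH"
  }

  emr_cohort(
    patients = data.table(patient_id = ids, age_years = age, sex = sex,
                          record_start = start, record_end = end),
    events = events,
    hemodynamics = hemodynamics,
    truth = data.table(patient_id = ids, truth_label = truth_label,
                       stratum = stratum)
  )
}
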