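test_that("configuration errors name the offending field", {
  expect_error(simulation_config(n_patients = -1), "n_patients")
  expect_error(simulation_config(pah_prevalence = 1.2), "pah_prevalence")
  expect_error(
    simulation_config(stratum_weights = c(postcapillary_ph = 0.5,
                                          offlabel_med_user = 0.03,
                                          code_only = 0.03,
                                          background = 0.88)),
    "stratum_weights")
  expect_error(
    simulation_config(record_span_days = list(mean = 100, sd = 10, min = 0)),
    "record_span_days")
})

test_that("degenerate cohort sizes behave", {
  empty <- simulate_cohort(simulation_config(n_patients = 0))
  expect_s3_class(empty, "emr_cohort")
  expect_equal(nrow(empty$patients), 0L)

  none <- simulate_cohort(simulation_config(
    n_patients = 300, pah_prevalence = 0,
    stratum_weights = c(postcapillary_ph = 0.05, offlabel_med_user = 0.03,
                        code_only = 0.04, background = 0.88), seed = 3))
  expect_equal(nrow(none$patients), 300L)
  expect_false(any(none$truth$truth_label == "PAH"))
})

test_that("equal config and seed give identical cohorts", {
  cfg <- simulation_config(n_patients = 2000, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$events, b$events)
  expect_identical(a$hemodynamics, b$hemodynamics)
  expect_identical(a$truth, b$truth)
})

test_that("every event lies within its record span", {
  co <- simulate_cohort(simulation_config(n_patients = 1000, seed = 5))
  ev <- merge(co$events, co$patients[, c("patient_id", "record_start",
                                         "record_end")], by = "patient_id")
  expect_true(all(ev$date >= ev$record_start & ev$date <= ev$record_end))
})

test_that("planted signal matches its stratum's screening signature", {
  cfg <- simulation_config(n_patients = 10)
  lex <- cfg$lexicon
  set.seed(11)
  for (i in 1:20) {
    base <- make_record(id = sprintf("B%02d", i), span = 2000)
    bg <- plant_signal(base, "background", cfg)
    expect_equal(screen_record(bg, lex)$n_features, 0L)
    off <- plant_signal(base, "offlabel_med_user", cfg)
    s_off <- screen_record(off, lex)
    expect_true(s_off$med)
    expect_false(s_off$icd)
    co <- plant_signal(base, "code_only", cfg)
    s_co <- screen_record(co, lex)
    expect_true(s_co$icd)
    expect_false(s_co$med || s_co$cpt)
  }
  expect_error(plant_signal(make_record(), "no_such_stratum", cfg),
               "unknown stratum")
})

test_that("true-PAH records screen positive in all three categories", {
  cfg <- simulation_config(n_patients = 10)
  set.seed(13)
  n_feats <- vapply(1:100, function(i) {
    rec <- plant_signal(make_record(id = sprintf("T%03d", i), span = 2500),
                        "true_pah", cfg)
    screen_record(rec, cfg$lexicon)$n_features
  }, integer(1))
  expect_true(all(n_feats == 3L))
})

test_that("synthetic truth equals the WSPH rule applied to hemodynamics", {
  co <- simulate_cohort(simulation_config(n_patients = 3000, seed = 17))
  rule <- adjudication_rule()
  ids <- co$patients$patient_id
  adj <- vapply(sample(ids, 400), function(id) {
    adjudicate(get_record(co, id), rule)
  }, character(1))
  truth <- co$truth$truth_label[match(names(adj), co$truth$patient_id)]
  expect_equal(unname(adj), truth)
})

test_that("PAH hemodynamics are calibrated to the truncated targets", {
  cfg <- simulation_config(n_patients = 10)
  set.seed(19)
  n <- 5000
  h <- pahphen:::sample_hemodynamics(
    n, cfg$hemodynamic_params$true_pah,
    pahphen:::hemo_constraints$true_pah, cfg$bsa_m2, adjudication_rule())
  oracle <- oracle_truncated_hemo(cfg$hemodynamic_params$true_pah,
                                  constraint = "wsph")
  for (v in c("mPAP", "PCWP", "PVR")) {
    tol <- 3 * oracle$sd[[v]] / sqrt(n)
    expect_lt(abs(mean(h[[v]]) - oracle$mean[[v]]), tol)
  }
  # CI derivation and PVR identity
  expect_equal(h$CI, h$CO / cfg$bsa_m2)
  expect_equal(h$PVR, (h$mPAP - h$PCWP) / h$CO)
})

test_that("post-capillary stratum always exceeds the wedge threshold", {
  co <- simulate_cohort(simulation_config(n_patients = 2000, seed = 23))
  pc <- co$truth$patient_id[co$truth$stratum == "postcapillary_ph"]
  h <- co$hemodynamics[co$hemodynamics$patient_id %in% pc]
  expect_gt(nrow(h), 0)
  expect_true(all(h$PCWP > 15))
})
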