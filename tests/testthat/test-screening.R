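lex <- default_lexicon()

test_that("category flags follow lexicon membership", {
  med_only <- make_record(events = make_events("2010-01-01", 30, "MED",
                                               "Adcirca"))
  r <- screen_record(med_only, lex)
  expect_true(r$flagged)
  expect_equal(r$n_features, 1L)
  expect_true(r$med)
  expect_false(r$icd || r$cpt)

  all3 <- make_record(events = rbind(
    make_events("2010-01-01", 10, "ICD10", "I27.0"),
    make_events("2010-01-01", 20, "CPT", "93501"),
    make_events("2010-01-01", 30, "MED", "epoprostenol")))
  r3 <- screen_record(all3, lex)
  expect_equal(r3$n_features, 3L)

  noise <- make_record(events = rbind(
    make_events("2010-01-01", 10, "ICD10", "I10"),
    make_events("2010-01-01", 20, "MED", "furosemide")))
  expect_false(screen_record(noise, lex)$flagged)

  empty <- make_record()
  expect_false(screen_record(empty, lex)$flagged)
})

test_that("review ranking sorts by feature count with id tie-break", {
  res <- data.frame(
    patient_id = c("D", "A", "C", "B", "E"),
    flagged = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    icd = FALSE, cpt = FALSE, med = FALSE,
    n_features = c(1L, 3L, 2L, 2L, 0L))
  expect_equal(rank_screened(res), c("A", "B", "C", "D"))

  none <- res; none$flagged <- FALSE; none$n_features <- 0L
  expect_equal(rank_screened(none), character())
})

test_that("adding a matching event never decreases the feature count", {
  cfg <- simulation_config(n_patients = 10)
  set.seed(31)
  for (i in 1:25) {
    stratum <- sample(c("background", "code_only", "offlabel_med_user",
                        "postcapillary_ph", "true_pah"), 1)
    rec <- plant_signal(make_record(span = 1500), stratum, cfg)
    before <- screen_record(rec, lex)$n_features
    extra_cat <- sample(c("icd", "cpt", "med"), 1)
    extra <- switch(extra_cat,
      icd = make_events(rec$record_start, 5, "ICD9", "416.0"),
      cpt = make_events(rec$record_start, 5, "CPT", "93451"),
      med = make_events(rec$record_start, 5, "MED", "Opsumit"))
    rec$events <- rbind(rec$events, extra)
    expect_gte(screen_record(rec, lex)$n_features, before)
  }
})

test_that("screening is blind to the truth label", {
  co <- simulate_cohort(simulation_config(n_patients = 400, seed = 37))
  base <- screen_cohort(co, lex)
  flipped <- co
  flipped$truth$truth_label <- rev(flipped$truth$truth_label)
  expect_identical(screen_cohort(flipped, lex), base)
})
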