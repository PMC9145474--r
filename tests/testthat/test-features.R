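lex <- default_lexicon()

test_that("strength/persistence/durability follow their definitions", {
  rec <- make_record(span = 200, events = make_events(
    "2010-01-01", c(10, 50, 100), "MED", "Adcirca"))
  fv <- extract_features(rec, lex)
  expect_equal(fv[["Adcirca__strength"]], 3)
  expect_equal(fv[["Adcirca__persistence"]], 90)
  expect_equal(fv[["Adcirca__durability"]], 90 / 190)
  # untouched variables stay at zero
  expect_equal(fv[["Flolan__strength"]], 0)
  expect_equal(fv[["Flolan__persistence"]], 0)
  expect_equal(fv[["Flolan__durability"]], 0)
})

test_that("a single mention on the final day scores (1, 0, 0)", {
  rec <- make_record(span = 100, events = make_events(
    "2010-01-01", 100, "MED", "Adcirca"))
  fv <- extract_features(rec, lex)
  expect_equal(fv[["Adcirca__strength"]], 1)
  expect_equal(fv[["Adcirca__persistence"]], 0)
  expect_equal(fv[["Adcirca__durability"]], 0)
})

test_that("same-day duplicate mentions each count toward strength", {
  rec <- make_record(span = 50, events = make_events(
    "2010-01-01", c(10, 10, 10), "CPT", "93501"))
  expect_equal(extract_features(rec, lex)[["93501__strength"]], 3)
})

test_that("an event outside the record span is a data-integrity error", {
  rec <- make_record(span = 100, events = make_events(
    "2010-01-01", 150, "MED", "Adcirca"))
  expect_error(extract_features(rec, lex), "outside the record span")
})

test_that("the feature matrix has a fixed, documented shape", {
  co <- simulate_cohort(simulation_config(n_patients = 100, seed = 47))
  fm <- build_feature_matrix(co, lex)
  n_vars <- length(lexicon_variables(lex))
  expect_equal(ncol(fm), 1 + 3 * n_vars)
  expect_equal(nrow(fm), 100)
  expect_equal(fm$patient_id, sort(co$patients$patient_id))
  expect_true(all(grepl("__(strength|persistence|durability)$",
                        names(fm)[-1])))

  # empty id set: zero rows, full header
  empty <- build_feature_matrix(co, lex, ids = character())
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty), names(fm))

  expect_error(build_feature_matrix(co, lex, ids = c("P000001", "P000001")),
               "duplicate")
})

test_that("row order is independent of the requested id order", {
  co <- simulate_cohort(simulation_config(n_patients = 80, seed = 53))
  ids <- co$patients$patient_id
  a <- build_feature_matrix(co, lex, ids = ids)
  b <- build_feature_matrix(co, lex, ids = rev(ids))
  expect_identical(a, b)
})

test_that("appending a later mention never decreases the triple", {
  set.seed(59)
  cfg <- simulation_config(n_patients = 10)
  for (i in 1:20) {
    rec <- plant_signal(make_record(span = 1000), "true_pah", cfg)
    fv0 <- extract_features(rec, lex)
    meds <- rec$events[rec$events$vocabulary == "MED", ]
    v <- meds$code[1]
    last_day <- as.numeric(max(meds$date[meds$code == v]) - rec$record_start)
    new_day <- sample(seq(last_day, 1000), 1)
    rec$events <- rbind(rec$events,
                        make_events(rec$record_start, new_day, "MED", v))
    fv1 <- extract_features(rec, lex)
    for (suffix in c("strength", "persistence", "durability")) {
      col <- paste0(v, "__", suffix)
      expect_gte(fv1[[col]], fv0[[col]])
    }
  }
})

test_that("production extractor matches the naive reference scan", {
  co <- simulate_cohort(simulation_config(n_patients = 150, seed = 61))
  fm <- build_feature_matrix(co, lex)
  ids <- sample(co$patients$patient_id, 25)
  for (id in ids) {
    ref <- oracle_features_naive(get_record(co, id), lex)
    got <- unlist(fm[fm$patient_id == id, -1])
    expect_equal(got, ref)
  }
})
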