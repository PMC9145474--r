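rule <- adjudication_rule()

hemo <- function(mPAP, PCWP, PVR) {
  co <- (mPAP - PCWP) / PVR  # back out CO so the PVR identity holds
  list(mRA = 8, mPAP = mPAP, PCWP = PCWP, CO = co, CI = co / 1.9, PVR = PVR)
}

test_that("the WSPH rule classifies hemodynamic profiles", {
  typical <- make_record(hemodynamics = hemo(49.8, 11.3, 9.9))
  expect_equal(adjudicate(typical, rule), "PAH")
  # thresholds are inclusive
  boundary <- make_record(hemodynamics = hemo(25, 15, 3))
  expect_equal(adjudicate(boundary, rule), "PAH")
  postcap <- make_record(hemodynamics = hemo(30, 18, 4))
  expect_equal(adjudicate(postcap, rule), "not_PAH")
  low_pvr <- make_record(hemodynamics = hemo(30, 10, 2.5))
  expect_equal(adjudicate(low_pvr, rule), "not_PAH")
})

test_that("records without catheterization data cannot be confirmed", {
  expect_equal(adjudicate(make_record(), rule), "not_PAH")
})

test_that("adjudication is idempotent and per-record", {
  rec <- make_record(hemodynamics = hemo(40, 10, 6))
  expect_equal(adjudicate(rec, rule), adjudicate(rec, rule))
})

test_that("review_batch honours the chart budget as an ordered prefix", {
  co <- simulate_cohort(simulation_config(n_patients = 500, seed = 41))
  ranked <- rank_screened(screen_cohort(co))
  expect_gt(length(ranked), 10)

  expect_equal(nrow(review_batch(ranked, co, rule, budget = 0)), 0L)

  all_lab <- review_batch(ranked, co, rule, budget = length(ranked) + 50)
  expect_equal(all_lab$patient_id, ranked)

  four <- review_batch(ranked, co, rule, budget = 4)
  expect_equal(four$patient_id, ranked[1:4])

  expect_error(review_batch(ranked, co, rule, budget = -1), "non-negative")
})

test_that("batch labels agree with per-record adjudication", {
  co <- simulate_cohort(simulation_config(n_patients = 300, seed = 43))
  ids <- co$patients$patient_id[1:40]
  batch <- review_batch(ids, co, rule, budget = 40)
  singles <- vapply(ids, function(id) adjudicate(get_record(co, id), rule),
                    character(1))
  expect_equal(batch$label, unname(singles))
})
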