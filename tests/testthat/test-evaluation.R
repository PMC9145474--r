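test_that("confusion metrics reproduce the closed-form ratios", {
  truth <- rep(c("PAH", "PAH", "not_PAH", "not_PAH"), c(50, 5, 10, 100))
  pred <- rep(c("PAH", "not_PAH", "PAH", "not_PAH"), c(50, 5, 10, 100))
  tc <- confusion_metrics(pred, truth)
  expect_equal(tc$tp, 50); expect_equal(tc$fn, 5)
  expect_equal(tc$fp, 10); expect_equal(tc$tn, 100)
  expect_equal(tc$sensitivity, 50 / 55)
  expect_equal(tc$specificity, 100 / 110)
  expect_equal(tc$ppv, 50 / 60)
  expect_equal(tc$npv, 100 / 105)

  perfect <- confusion_metrics(truth, truth)
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$ppv,
                 perfect$npv), rep(1, 4))

  nopos <- confusion_metrics(rep("not_PAH", 10),
                             rep(c("PAH", "not_PAH"), c(3, 7)))
  expect_true(is.na(nopos$ppv))
  expect_equal(nopos$sensitivity, 0)

  expect_error(confusion_metrics("PAH", c("PAH", "PAH")), "length")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(67)
  for (i in 1:50) {
    counts <- rmultinom(1, sample(20:200, 1), prob = runif(4, 0.05, 1))[, 1]
    truth <- rep(c("PAH", "PAH", "not_PAH", "not_PAH"), counts)
    pred <- rep(c("PAH", "not_PAH", "PAH", "not_PAH"), counts)
    tc <- confusion_metrics(pred, truth)
    expect_equal(tc$tp + tc$fp + tc$fn + tc$tn, tc$n)
    # independent arithmetic straight from the counts
    if (counts[1] + counts[2] > 0) {
      expect_equal(tc$sensitivity, counts[1] / (counts[1] + counts[2]),
                   tolerance = 1e-12)
    }
    if (counts[3] + counts[4] > 0) {
      expect_equal(tc$specificity, counts[4] / (counts[3] + counts[4]),
                   tolerance = 1e-12)
    }
  }
})

test_that("rank-based AUC equals brute-force pair counting", {
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.2),
                         c("PAH", "PAH", "not_PAH", "not_PAH")), 1)
  expect_equal(auc_score(rep(0.3, 8),
                         rep(c("PAH", "not_PAH"), 4)), 0.5)
  expect_error(auc_score(runif(5), rep("PAH", 5)), "both classes")

  set.seed(71)
  for (i in 1:10) {
    n <- 50
    scores <- round(runif(n), 2)  # coarse grid forces ties
    truth <- sample(c("PAH", "not_PAH"), n, replace = TRUE,
                    prob = c(0.3, 0.7))
    if (length(unique(truth)) < 2) next
    expect_equal(auc_score(scores, truth),
                 oracle_auc_paircount(scores, truth))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(73)
  scores <- rnorm(60)
  truth <- sample(c("PAH", "not_PAH"), 60, replace = TRUE)
  base <- auc_score(scores, truth)
  expect_equal(auc_score(exp(scores), truth), base)
  expect_equal(auc_score(2 * scores - 5, truth), base)
  expect_equal(auc_score(rank(scores), truth), base)
})

test_that("resampling confidence intervals follow the normal formula", {
  const <- resample_ci(rep(0.8, 10))
  expect_equal(unname(const), c(0.8, 0.8, 0.8))

  two <- resample_ci(c(0.9, 1.0))
  expect_equal(unname(two["mean"]), 0.95)
  hw <- qnorm(0.975) * sd(c(0.9, 1.0)) / sqrt(2)
  expect_equal(unname(two["mean"] - two["low"]), hw, tolerance = 1e-10)
  expect_equal(unname(two["high"]), 1)  # clipped at the probability ceiling

  expect_error(resample_ci(0.5), "at least 2")
})

test_that("normal-approximation intervals achieve near-nominal coverage", {
  set.seed(79)
  covered <- 0L
  for (r in 1:100) {
    ci <- resample_ci(rnorm(30, 0.94, 0.01))
    if (ci["low"] <= 0.94 && 0.94 <= ci["high"]) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
})

test_that("the case summary aggregates demographics and hemodynamics", {
  empty <- characteristics_table(character(), make_separable_cohort())
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$age_mean))

  start <- as.Date("2010-01-01")
  recs <- list(
    patient_record("A", 40, "female", start, start + 100),
    patient_record("B", 60, "male", start, start + 100))
  co <- pahphen:::records_to_cohort(recs)
  s <- characteristics_table(c("A", "B"), co)
  expect_equal(s$n, 2L)
  expect_equal(s$age_mean, 50)
  expect_equal(s$age_sd, sd(c(40, 60)))
  expect_equal(s$pct_female, 50)
  expect_equal(s$n_hemodynamics, 0L)
  expect_setequal(s$hemodynamics$measure,
                  c("mRA", "mPAP", "PCWP", "CO", "CI", "PVR"))
})

test_that("medication-class percentages count exposed patients once", {
  co <- make_separable_cohort(n_cases = 4, n_controls = 2)
  ids <- co$truth$patient_id[co$truth$truth_label == "PAH"]
  s <- characteristics_table(ids, co)
  expect_equal(unname(s$med_class_pct["prostanoid"]), 100)  # all on Flolan
  expect_equal(unname(s$med_class_pct["era"]), 0)
})
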