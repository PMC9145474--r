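test_that("lexicon construction validates its inputs", {
  expect_error(pah_lexicon(character(), "93501", list(a = "A")), "icd_codes")
  expect_error(pah_lexicon("416.0", "93501",
                           list(epoprostenol = "Flolan",
                                treprostinil = "flolan")),
               "maps to more than one generic")
  expect_error(pah_lexicon("416.0", "93501", list()), "medications")
})

test_that("variable sets reflect the alias mode", {
  sep <- default_lexicon(collapse_aliases = FALSE)
  pooled <- default_lexicon(collapse_aliases = TRUE)
  v_sep <- lexicon_variables(sep)
  v_pooled <- lexicon_variables(pooled)
  # brands are their own variables in separate mode
  expect_true(all(c("Flolan", "epoprostenol", "Adcirca") %in% v_sep))
  expect_false("Flolan" %in% v_pooled)
  expect_true("epoprostenol" %in% v_pooled)
  expect_length(v_pooled, length(sep$icd_codes) + length(sep$cpt_codes) +
                  length(sep$medications))
})

test_that("alias matching is case-insensitive and pools under collapse", {
  pooled <- default_lexicon(collapse_aliases = TRUE)
  rec <- make_record(events = rbind(
    make_events("2010-01-01", c(0, 100), "MED", "FLOLAN"),
    make_events("2010-01-01", 200, "MED", "epoprostenol")))
  fv <- extract_features(rec, pooled)
  expect_equal(fv[["epoprostenol__strength"]], 3)
  expect_equal(fv[["epoprostenol__persistence"]], 200)
})

test_that("lexicon YAML round-trips", {
  lex <- default_lexicon()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_lexicon(lex, path)
  back <- read_lexicon(path)
  expect_equal(back$icd_codes, lex$icd_codes)
  expect_equal(back$cpt_codes, lex$cpt_codes)
  expect_equal(back$medications, lex$medications)
  expect_error(read_lexicon(file.path(tempdir(), "nope.yaml")), "not found")
})
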