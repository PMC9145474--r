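#' Three-category screening tool for possible PAH
#'
#' A record screens positive ("flagged") when it carries at least one coded
#' feature suggestive of PAH: an ICD-9/10 code for primary pulmonary
#' hypertension, a right-heart-catheterization CPT code variant, or a
#' PAH-specific medication mention (brand or generic, case-insensitive).
#' `n_features` counts how many of the three categories are present, which is
#' what the review queue is sorted by.
#'
#' Screening is label-blind: it is a pure function of the events and the
#' lexicon.
#'
#' @param record a `patient_record`.
#' @param lexicon a `pah_lexicon`.
#' @return a one-row data.table: `patient_id`, `flagged`, `icd`, `cpt`,
#'   `med`, `n_features`.
#' @export
#' @examples
#' lex <- default_lexicon()
#' rec <- patient_record("A", 50, "female", "2010-01-01", "2012-01-01",
#'   events = data.frame(date = as.Date("2011-05-01"),
#'                       vocabulary = "MED", code = "Adcirca"))
#' screen_record(rec, lex)
screen_record <- function(record, lexicon = default_lexicon()) {
  stopifnot(inherits(record, "patient_record"))
  ev <- record$events
  cohort_like <- data.table(
    patient_id = record$patient_id,
    date = ev$date, vocabulary = ev$vocabulary, code = ev$code)
  screen_events(cohort_like, record$patient_id, lexicon)
}

# shared implementation over a long events table for a set of ids
screen_events <- function(events, ids, lexicon) {
  mt <- lexicon_match_table(lexicon)
  hits <- match_events(events, mt)
  flags <- dcast.data.table(
    hits[, .(hit = .N > 0L), by = .(patient_id, category)],
    patient_id ~ category, value.var = "hit", fill = FALSE)
  for (cat in c("icd", "cpt", "med")) {
    if (!cat %in% names(flags)) flags[, (cat) := FALSE]
  }
  out <- data.table(patient_id = as.character(ids))
  m <- match(out$patient_id, flags$patient_id)
  for (cat in c("icd", "cpt", "med")) {
    v <- flags[[cat]][m]
    out[, (cat) := !is.na(v) & v]
  }
  out[, n_features := as.integer(icd) + as.integer(cpt) + as.integer(med)]
  out[, flagged := n_features >= 1L]
  out[, .(patient_id, flagged, icd, cpt, med, n_features)]
}

# join events against the lexicon lookup (ICD9/ICD10 normalize to ICD)
match_events <- function(events, match_table) {
  if (nrow(events) == 0L) {
    return(data.table(patient_id = character(), date = as.Date(character()),
                      variable = character(), category = character()))
  }
  ev <- data.table(
    patient_id = events$patient_id, date = events$date,
    vocabulary = ifelse(events$vocabulary %in% c("ICD9", "ICD10"), "ICD",
                        events$vocabulary),
    code_lower = tolower(events$code))
  merge(ev, match_table, by = c("vocabulary", "code_lower"),
        allow.cartesian = FALSE)[, .(patient_id, date, variable, category)]
}

#' Screen every patient in a cohort
#'
#' @param cohort an `emr_cohort`.
#' @param lexicon a `pah_lexicon`.
#' @return data.table with one row per patient (`patient_id`, `flagged`,
#'   `icd`, `cpt`, `med`, `n_features`), in patients-table order.
#' @export
screen_cohort <- function(cohort, lexicon = default_lexicon()) {
  stopifnot(inherits(cohort, "emr_cohort"))
  screen_events(cohort$events, cohort$patients$patient_id, lexicon)
}

#' Rank screened patients for chart review
#'
#' Flagged patients sorted by `n_features` descending (records carrying all
#' three evidence categories first); ties broken by ascending patient id for
#' determinism. Unflagged patients are excluded.
#'
#' @param results screening table from [screen_cohort()] /
#'   [screen_record()] rows.
#' @return character vector of patient ids in review order.
#' @export
rank_screened <- function(results) {
  res <- as.data.table(results)
  if (nrow(res) == 0L) return(character())
  res <- res[flagged == TRUE]
  setorder(res, -n_features, patient_id)
  res$patient_id
}
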