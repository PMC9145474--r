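#' Strength / persistence / durability feature calculus
#'
#' Every screened variable (each lexicon ICD code, CPT code and medication
#' name) contributes three longitudinal features per patient:
#'
#' * **strength** — the number of mentions throughout the record (same-day
#'   duplicates each count);
#' * **persistence** — the number of whole days the variable stayed on the
#'   record, i.e. last mention minus first mention (a single mention persists
#'   0 days);
#' * **durability** — persistence divided by the length of the record after
#'   the first mention (`record_end - first`), so a variable mentioned
#'   continuously until the end of the record approaches 1 while an isolated
#'   late mention scores 0. The degenerate 0/0 case (single mention on the
#'   final day) is defined as 0.
#'
#' Variables with no mentions score (0, 0, 0).
#'
#' @param record a `patient_record` whose events all lie within its span.
#' @param lexicon a `pah_lexicon`.
#' @return a one-row data.frame: `patient_id` followed by
#'   `{variable}__strength`, `{variable}__persistence`,
#'   `{variable}__durability` for every lexicon variable, in lexicon order.
#' @export
#' @examples
#' lex <- default_lexicon()
#' rec <- patient_record("A", 50, "female", "2010-01-01",
#'   as.Date("2010-01-01") + 200,
#'   events = data.frame(date = as.Date("2010-01-01") + c(10, 50, 100),
#'                       vocabulary = "MED", code = "Adcirca"))
#' fv <- extract_features(rec, lex)
#' fv[["Adcirca__strength"]]     # 3
#' fv[["Adcirca__persistence"]]  # 90
#' fv[["Adcirca__durability"]]   # 90 / 190
extract_features <- function(record, lexicon = default_lexicon()) {
  stopifnot(inherits(record, "patient_record"))
  ev <- record$events
  if (nrow(ev) > 0L) {
    bad <- which(ev$date < record$record_start | ev$date > record$record_end)
    if (length(bad)) {
      stop("event ", bad[1L], " (", ev$vocabulary[bad[1L]], " ",
           ev$code[bad[1L]], " on ", ev$date[bad[1L]],
           ") lies outside the record span of patient ", record$patient_id)
    }
  }
  events <- data.table(patient_id = record$patient_id, date = ev$date,
                       vocabulary = ev$vocabulary, code = ev$code)
  spans <- data.table(patient_id = record$patient_id,
                      record_end = record$record_end)
  as.data.frame(feature_matrix_core(events, spans, record$patient_id, lexicon))
}

# vectorized core: per (patient, variable) aggregate over matched events,
# then cast to the fixed wide layout
feature_matrix_core <- function(events, spans, ids, lexicon) {
  vars <- lexicon_variables(lexicon)
  hits <- match_events(events, lexicon_match_table(lexicon))
  out <- data.table(patient_id = as.character(ids))
  setkey(out, NULL)
  cols <- as.vector(t(outer(vars, c("strength", "persistence", "durability"),
                            paste, sep = "__")))
  for (cn in cols) out[, (cn) := 0]
  if (nrow(hits) > 0L) {
    agg <- hits[, .(strength = .N, first_date = min(date),
                    last_date = max(date)),
                by = .(patient_id, variable)]
    agg <- merge(agg, spans, by = "patient_id")
    agg[, persistence := as.numeric(last_date - first_date)]
    tail_days <- as.numeric(agg$record_end - agg$first_date)
    agg[, durability := ifelse(tail_days > 0, persistence / tail_days, 0)]
    m <- match(agg$patient_id, out$patient_id)
    for (v in unique(agg$variable)) {
      sel <- agg$variable == v
      rows <- m[sel]
      data.table::set(out, i = rows, j = paste0(v, "__strength"),
                      value = as.numeric(agg$strength[sel]))
      data.table::set(out, i = rows, j = paste0(v, "__persistence"),
                      value = agg$persistence[sel])
      data.table::set(out, i = rows, j = paste0(v, "__durability"),
                      value = agg$durability[sel])
    }
  }
  out
}

#' Build the cohort feature matrix
#'
#' One row per requested patient, `3 * n_variables` feature columns in the
#' fixed order strength/persistence/durability nested within lexicon variable
#' order; rows sorted by patient id. Patients with no matching mentions (e.g.
#' unflagged patients during deployment) receive all-zero rows.
#'
#' @param cohort an `emr_cohort`.
#' @param lexicon a `pah_lexicon`.
#' @param ids patient ids to include (default: every patient in the cohort).
#' @return data.frame of features keyed by `patient_id`.
#' @export
build_feature_matrix <- function(cohort, lexicon = default_lexicon(),
                                 ids = NULL) {
  stopifnot(inherits(cohort, "emr_cohort"))
  ids <- as.character(ids %||% cohort$patients$patient_id)
  if (anyDuplicated(ids)) stop("duplicate patient ids requested")
  unknown <- setdiff(ids, cohort$patients$patient_id)
  if (length(unknown)) stop("unknown patient ids: ",
                            paste(utils::head(unknown, 3L), collapse = ", "))
  ids <- sort(ids)
  events <- cohort$events[cohort$events$patient_id %in% ids]
  spans <- cohort$patients[cohort$patients$patient_id %in% ids,
                           .(patient_id, record_end)]
  as.data.frame(feature_matrix_core(events, spans, ids, lexicon))
}
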