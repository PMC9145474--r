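#' EMR cohort container
#'
#' A cohort is a set of four aligned tables, mirroring how de-identified EMR
#' extracts are delivered: `patients` (one row per patient: demographics and
#' record span), `events` (long format: one dated coded mention per row),
#' `hemodynamics` (one optional right-heart-catheterization row per patient),
#' and — for synthetic cohorts only — `truth` (latent label and generating
#' stratum). The truth table is carried in a separate slot so that screening,
#' feature extraction and modelling can never read it by accident; only the
#' adjudication oracle closes the loop against it in tests.
#'
#' @param patients data.frame with columns `patient_id`, `age_years`, `sex`
#'   ("female"/"male"), `record_start`, `record_end` (Date).
#' @param events data.frame with columns `patient_id`, `date` (Date),
#'   `vocabulary` (one of ICD9, ICD10, CPT, MED), `code`.
#' @param hemodynamics optional data.frame with columns `patient_id`, `mRA`,
#'   `mPAP`, `PCWP`, `CO`, `CI`, `PVR`.
#' @param truth optional data.frame with columns `patient_id`, `truth_label`
#'   ("PAH"/"not_PAH"), `stratum`.
#' @param validate run integrity checks (span containment, vocabularies,
#'   orphan events)?
#' @return an object of class `emr_cohort`.
#' @export
emr_cohort <- function(patients, events, hemodynamics = NULL, truth = NULL,
                       validate = TRUE) {
  patients <- as.data.table(patients)
  events <- as.data.table(events)
  hemodynamics <- if (!is.null(hemodynamics)) as.data.table(hemodynamics)
  truth <- if (!is.null(truth)) as.data.table(truth)
  obj <- structure(
    list(patients = patients, events = events,
         hemodynamics = hemodynamics, truth = truth),
    class = "emr_cohort"
  )
  if (validate) validate_cohort(obj)
  obj
}

valid_vocabularies <- c("ICD9", "ICD10", "CPT", "MED")

validate_cohort <- function(cohort) {
  p <- cohort$patients
  e <- cohort$events
  need_p <- c("patient_id", "age_years", "sex", "record_start", "record_end")
  if (!all(need_p %in% names(p))) {
    stop("patients table missing columns: ",
         paste(setdiff(need_p, names(p)), collapse = ", "))
  }
  if (anyDuplicated(p$patient_id)) stop("duplicate patient ids in patients table")
  if (any(p$record_start > p$record_end)) {
    bad <- p$patient_id[which(p$record_start > p$record_end)][1L]
    stop("record_start after record_end for patient ", bad)
  }
  if (nrow(e) > 0L) {
    need_e <- c("patient_id", "date", "vocabulary", "code")
    if (!all(need_e %in% names(e))) {
      stop("events table missing columns: ",
           paste(setdiff(need_e, names(e)), collapse = ", "))
    }
    bad_voc <- which(!e$vocabulary %in% valid_vocabularies)
    if (length(bad_voc)) {
      stop("unknown vocabulary '", e$vocabulary[bad_voc[1L]],
           "' at events row ", bad_voc[1L])
    }
    orphan <- which(!e$patient_id %in% p$patient_id)
    if (length(orphan)) {
      stop("event for unknown patient '", e$patient_id[orphan[1L]],
           "' at events row ", orphan[1L])
    }
    span <- p[, .(patient_id, record_start, record_end)]
    ev <- merge(e[, .(patient_id, date, row = .I)], span, by = "patient_id")
    out <- ev[date < record_start | date > record_end]
    if (nrow(out)) {
      stop("event at row ", out$row[1L], " dated ", out$date[1L],
           " lies outside record span of patient ", out$patient_id[1L])
    }
  }
  h <- cohort$hemodynamics
  if (!is.null(h) && nrow(h) > 0L) {
    if (anyDuplicated(h$patient_id)) stop("duplicate hemodynamics rows")
    rel <- abs(h$PVR - (h$mPAP - h$PCWP) / h$CO) /
      pmax(abs(h$PVR), .Machine$double.eps)
    if (any(rel > 1e-6)) {
      stop("PVR inconsistent with (mPAP - PCWP)/CO for patient ",
           h$patient_id[which(rel > 1e-6)[1L]])
    }
    if (any(h$CO <= 0) || any(h[, c("mRA", "mPAP", "PCWP")] < 0)) {
      stop("hemodynamic pressures must be >= 0 and CO > 0")
    }
  }
  invisible(cohort)
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat("<emr_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$events), " events, ",
      if (is.null(x$hemodynamics)) 0L else nrow(x$hemodynamics),
      " hemodynamic rows",
      if (!is.null(x$truth)) " [synthetic: truth table attached]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Extract one patient as a standalone record
#'
#' @param cohort an `emr_cohort`.
#' @param patient_id one patient id present in the cohort.
#' @return a `patient_record`: a list with the patient's demographics, span,
#'   events table, and optional hemodynamics / synthetic truth fields.
#' @export
get_record <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "emr_cohort"))
  pid <- patient_id
  row <- cohort$patients[cohort$patients$patient_id == pid]
  if (nrow(row) != 1L) stop("unknown patient id: ", pid)
  hemo <- NULL
  if (!is.null(cohort$hemodynamics)) {
    h <- cohort$hemodynamics[cohort$hemodynamics$patient_id == pid]
    if (nrow(h) == 1L) hemo <- as.list(h[, -"patient_id"])
  }
  tl <- st <- NULL
  if (!is.null(cohort$truth)) {
    t <- cohort$truth[cohort$truth$patient_id == pid]
    if (nrow(t) == 1L) { tl <- t$truth_label; st <- t$stratum }
  }
  patient_record(
    patient_id = row$patient_id, age_years = row$age_years, sex = row$sex,
    record_start = row$record_start, record_end = row$record_end,
    events = cohort$events[cohort$events$patient_id == pid,
                           .(date, vocabulary, code)],
    hemodynamics = hemo, truth_label = tl, stratum = st
  )
}

#' @rdname get_record
#' @param age_years,sex,record_start,record_end demographics and record span.
#' @param events data.frame of `date`, `vocabulary`, `code` (may be empty).
#' @param hemodynamics optional named list (mRA, mPAP, PCWP, CO, CI, PVR).
#' @param truth_label,stratum synthetic-only latent fields.
#' @export
patient_record <- function(patient_id, age_years, sex, record_start,
                           record_end, events = NULL, hemodynamics = NULL,
                           truth_label = NULL, stratum = NULL) {
  if (is.null(events)) {
    events <- data.table(date = as.Date(character()),
                         vocabulary = character(), code = character())
  }
  events <- as.data.table(events)
  structure(
    list(patient_id = as.character(patient_id), age_years = age_years,
         sex = sex, record_start = as.Date(record_start),
         record_end = as.Date(record_end), events = events,
         hemodynamics = hemodynamics, truth_label = truth_label,
         stratum = stratum),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record> ", x$patient_id, ": ", x$sex, ", ",
      round(x$age_years), "y, span ", format(x$record_start), " .. ",
      format(x$record_end), ", ", nrow(x$events), " events",
      if (!is.null(x$hemodynamics)) ", RHC hemodynamics" else "",
      "\n", sep = "")
  invisible(x)
}

# bind a list of patient_records back into an emr_cohort
records_to_cohort <- function(records, validate = TRUE) {
  patients <- rbindlist(lapply(records, function(r) {
    data.table(patient_id = r$patient_id, age_years = r$age_years,
               sex = r$sex, record_start = r$record_start,
               record_end = r$record_end)
  }))
  events <- rbindlist(lapply(records, function(r) {
    if (nrow(r$events) == 0L) return(NULL)
    data.table(patient_id = r$patient_id, r$events)
  }))
  if (nrow(events) == 0L) {
    events <- data.table(patient_id = character(),
                         date = as.Date(character()),
                         vocabulary = character(), code = character())
  }
  hemo <- rbindlist(lapply(records, function(r) {
    if (is.null(r$hemodynamics)) return(NULL)
    data.table(patient_id = r$patient_id, as.data.table(r$hemodynamics))
  }))
  if (nrow(hemo) == 0L) hemo <- NULL
  truth <- rbindlist(lapply(records, function(r) {
    if (is.null(r$truth_label)) return(NULL)
    data.table(patient_id = r$patient_id, truth_label = r$truth_label,
               stratum = r$stratum %||% NA_character_)
  }))
  if (nrow(truth) == 0L) truth <- NULL
  emr_cohort(patients, events, hemo, truth, validate = validate)
}
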