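#' Hemodynamic chart-review oracle
#'
#' Manual chart review in the source workflow confirms PAH from a right heart
#' catheterization (RHC) showing pre-capillary hemodynamics under the World
#' Symposium on Pulmonary Hypertension (WSPH) definition: mean pulmonary
#' artery pressure (mPAP) >= 25 mmHg, pulmonary vascular resistance (PVR)
#' >= 3 Wood units, and pulmonary capillary wedge pressure (PCWP) <= 15 mmHg.
#' `adjudicate()` is the simulated reviewer: it applies that rule to a
#' record's hemodynamics. Records with no RHC hemodynamics cannot be
#' confirmed and adjudicate to `not_PAH`. All thresholds are inclusive.
#'
#' @param mpap_min,pvr_min,pcwp_max hemodynamic thresholds (mmHg, Wood units,
#'   mmHg).
#' @param adult_age_min minimum age in years used when assembling the final
#'   cohort (younger development-cohort patients are excluded there, not
#'   here).
#' @return an `adjudication_rule` object.
#' @export
#' @examples
#' rule <- adjudication_rule()
#' rec <- patient_record("X", 50, "female", "2010-01-01", "2015-01-01",
#'   hemodynamics = list(mRA = 10, mPAP = 49.8, PCWP = 11.3,
#'                       CO = 4.8, CI = 4.8 / 1.9, PVR = (49.8 - 11.3) / 4.8))
#' adjudicate(rec, rule)  # "PAH"
adjudication_rule <- function(mpap_min = 25, pvr_min = 3, pcwp_max = 15,
                              adult_age_min = 18) {
  stopifnot(mpap_min > 0, pvr_min > 0, pcwp_max > 0, adult_age_min > 0)
  structure(list(mpap_min = mpap_min, pvr_min = pvr_min, pcwp_max = pcwp_max,
                 adult_age_min = adult_age_min),
            class = "adjudication_rule")
}

# vectorized WSPH test over hemodynamic columns
wsph_pass <- function(mPAP, PCWP, PVR, rule) {
  mPAP >= rule$mpap_min & PVR >= rule$pvr_min & PCWP <= rule$pcwp_max
}

#' @rdname adjudication_rule
#' @param record a `patient_record`.
#' @param rule an `adjudication_rule`.
#' @export
adjudicate <- function(record, rule = adjudication_rule()) {
  stopifnot(inherits(record, "patient_record"),
            inherits(rule, "adjudication_rule"))
  h <- record$hemodynamics
  if (is.null(h)) return("not_PAH")
  if (wsph_pass(h$mPAP, h$PCWP, h$PVR, rule)) "PAH" else "not_PAH"
}

# cohort-level adjudication for a set of ids (the per-record loop is the
# contract; this is the same rule applied through the hemodynamics table)
adjudicate_ids <- function(cohort, ids, rule = adjudication_rule()) {
  lab <- rep("not_PAH", length(ids))
  h <- cohort$hemodynamics
  if (!is.null(h) && nrow(h) > 0L) {
    hh <- h[match(ids, h$patient_id)]
    ok <- !is.na(hh$mPAP) & wsph_pass(hh$mPAP, hh$PCWP, hh$PVR, rule)
    lab[ok] <- "PAH"
  }
  data.table(patient_id = as.character(ids), label = lab)
}

#' Adjudicate a review batch under a chart budget
#'
#' Works through an ordered candidate list (typically the output of
#' [rank_screened()]) and adjudicates the first `min(budget, n)` candidates;
#' the remainder are left unreviewed.
#'
#' @param candidates ordered character vector of patient ids.
#' @param cohort an `emr_cohort` holding the candidates.
#' @param rule an `adjudication_rule`.
#' @param budget non-negative integer number of charts that can be reviewed.
#' @return data.table with columns `patient_id`, `label` for the reviewed
#'   prefix, in review order.
#' @export
review_batch <- function(candidates, cohort, rule = adjudication_rule(),
                         budget) {
  if (length(budget) != 1L || is.na(budget) || budget < 0) {
    stop("review budget must be a non-negative integer")
  }
  take <- utils::head(candidates, budget)
  if (length(take) == 0L) {
    return(data.table(patient_id = character(), label = character()))
  }
  adjudicate_ids(cohort, take, rule)
}
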