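#' Diagnostic test characteristics from predicted and true labels
#'
#' Computes the confusion matrix and the classical claims-validation metrics:
#' sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive value
#' tp/(tp+fp) and negative predictive value tn/(tn+fn). A ratio with a zero
#' denominator is reported as `NA` (undefined), never as 0.
#'
#' @param predicted,truth equal-length vectors of labels.
#' @param positive the label counted as a case (default "PAH").
#' @return a `test_characteristics` object (list with `n`, `tp`, `fp`, `fn`,
#'   `tn`, `sensitivity`, `specificity`, `ppv`, `npv`, and `auc` slot filled
#'   by callers that also have scores).
#' @export
#' @examples
#' confusion_metrics(rep(c("PAH", "not_PAH"), c(60, 105)),
#'                   rep(c("PAH", "not_PAH", "PAH", "not_PAH"),
#'                       c(50, 10, 5, 100)))
confusion_metrics <- function(predicted, truth, positive = "PAH") {
  if (length(predicted) != length(truth)) {
    stop("predicted and true label vectors differ in length (",
         length(predicted), " vs ", length(truth), ")")
  }
  p <- predicted == positive
  t <- truth == positive
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(n = length(truth), tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = safe_div(tp, tp + fn),
         specificity = safe_div(tn, tn + fp),
         ppv = safe_div(tp, tp + fp),
         npv = safe_div(tn, tn + fn),
         auc = NA_real_),
    class = "test_characteristics"
  )
}

#' @export
print.test_characteristics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat("<test_characteristics> n=", x$n,
      " (tp=", x$tp, " fp=", x$fp, " fn=", x$fn, " tn=", x$tn, ")\n",
      "  AUC=", fmt(x$auc), " Se=", fmt(x$sensitivity),
      " Sp=", fmt(x$specificity), " PPV=", fmt(x$ppv),
      " NPV=", fmt(x$npv), "\n", sep = "")
  invisible(x)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random case scores above a random non-case, with tied
#' scores contributing 1/2 — i.e. the Mann-Whitney U statistic scaled to
#' `[0, 1]`, computed from mid-ranks. Equal to brute-force pair counting.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param truth labels; both classes must be present.
#' @param positive the case label.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, truth, positive = "PAH") {
  if (length(scores) != length(truth)) stop("scores/labels length mismatch")
  y <- truth == positive
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC requires both classes present (cases=", n1, ", non-cases=", n0, ")")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Normal-approximation confidence interval over resampled metric values
#'
#' Summarizes fold-level metrics (e.g. the 30 AUCs from tenfold
#' cross-validation repeated 3 times) as mean +/- z * sd/sqrt(k), clipped to
#' `[0, 1]`. A percentile alternative is available.
#'
#' @param samples numeric vector of at least 2 metric values.
#' @param level confidence level.
#' @param method "normal" (default) or "percentile".
#' @return named numeric: `mean`, `low`, `high`.
#' @export
resample_ci <- function(samples, level = 0.95, method = c("normal", "percentile")) {
  method <- match.arg(method)
  if (length(samples) < 2L) stop("resample_ci needs at least 2 samples")
  m <- mean(samples)
  if (method == "normal") {
    z <- qnorm(1 - (1 - level) / 2)
    hw <- z * sd(samples) / sqrt(length(samples))
    lo <- m - hw; hi <- m + hw
  } else {
    qs <- stats::quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    lo <- qs[1L]; hi <- qs[2L]
  }
  c(mean = m, low = max(0, lo), high = min(1, hi))
}

#' Registry-style summary of predicted PAH cases
#'
#' Aggregates the patients a model flags during deployment the way PAH
#' registries report their cohorts: n; age mean (SD); % female; % connective
#' tissue disease and % congenital heart disease by ICD code; exposure to
#' each PAH medication class; and right-heart-catheterization hemodynamic
#' means (SD) over the subset of cases that have hemodynamic data, with that
#' sub-n reported.
#'
#' @param case_ids patient ids predicted positive.
#' @param cohort an `emr_cohort`.
#' @param lexicon a `pah_lexicon` (for medication-class membership).
#' @param med_classes named list of generic names per class.
#' @param comorbidity_codes named list (`ctd`, `chd`) of ICD codes.
#' @return a `case_summary` list: `n`, `age_mean`, `age_sd`, `pct_female`,
#'   `pct_ctd`, `pct_chd`, `med_class_pct` (named), `n_hemodynamics`, and
#'   `hemodynamics` (data.frame of mean/sd per measure).
#' @export
characteristics_table <- function(case_ids, cohort,
                                  lexicon = default_lexicon(),
                                  med_classes = default_med_classes(),
                                  comorbidity_codes = default_comorbidity_codes()) {
  stopifnot(inherits(cohort, "emr_cohort"))
  case_ids <- as.character(case_ids)
  n <- length(case_ids)
  hemo_measures <- c("mRA", "mPAP", "PCWP", "CO", "CI", "PVR")
  if (n == 0L) {
    return(structure(
      list(n = 0L, age_mean = NA_real_, age_sd = NA_real_,
           pct_female = NA_real_, pct_ctd = NA_real_, pct_chd = NA_real_,
           med_class_pct = stats::setNames(rep(NA_real_, length(med_classes)),
                                           names(med_classes)),
           n_hemodynamics = 0L,
           hemodynamics = data.frame(measure = hemo_measures,
                                     mean = NA_real_, sd = NA_real_)),
      class = "case_summary"))
  }
  pts <- cohort$patients[cohort$patients$patient_id %in% case_ids]
  ev <- cohort$events[cohort$events$patient_id %in% case_ids]
  code_pct <- function(codes) {
    100 * length(unique(ev$patient_id[ev$code %in% codes])) / n
  }
  med_pct <- vapply(names(med_classes), function(cl) {
    aliases <- med_class_aliases(lexicon, med_classes[[cl]])
    hit <- ev$vocabulary == "MED" & tolower(ev$code) %in% aliases
    100 * length(unique(ev$patient_id[hit])) / n
  }, numeric(1L))
  h <- cohort$hemodynamics
  hsub <- if (!is.null(h)) h[h$patient_id %in% case_ids] else NULL
  nh <- if (is.null(hsub)) 0L else nrow(hsub)
  hemo <- data.frame(
    measure = hemo_measures,
    mean = vapply(hemo_measures, function(v)
      if (nh > 0L) mean(hsub[[v]]) else NA_real_, numeric(1L)),
    sd = vapply(hemo_measures, function(v)
      if (nh > 1L) sd(hsub[[v]]) else NA_real_, numeric(1L)),
    row.names = NULL)
  structure(
    list(n = n,
         age_mean = mean(pts$age_years),
         age_sd = if (n > 1L) sd(pts$age_years) else NA_real_,
         pct_female = 100 * mean(pts$sex == "female"),
         pct_ctd = code_pct(comorbidity_codes$ctd),
         pct_chd = code_pct(comorbidity_codes$chd),
         med_class_pct = med_pct,
         n_hemodynamics = nh,
         hemodynamics = hemo),
    class = "case_summary")
}

#' @export
print.case_summary <- function(x, ...) {
  cat("<case_summary> n=", x$n, "\n", sep = "")
  if (x$n > 0L) {
    cat(sprintf("  age %.1f (%.1f); %.1f%% female; CTD %.1f%%; CHD %.1f%%\n",
                x$age_mean, x$age_sd, x$pct_female, x$pct_ctd, x$pct_chd))
    cat("  medication classes:",
        paste(sprintf("%s %.1f%%", names(x$med_class_pct), x$med_class_pct),
              collapse = ", "), "\n")
    cat("  hemodynamics (n=", x$n_hemodynamics, "):\n", sep = "")
    for (i in seq_len(nrow(x$hemodynamics))) {
      cat(sprintf("    %-4s %.1f (%.1f)\n", x$hemodynamics$measure[i],
                  x$hemodynamics$mean[i], x$hemodynamics$sd[i]))
    }
  }
  invisible(x)
}
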