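#' Screening lexicon of PAH-suggestive codes and medications
#'
#' The screening tool looks for three categories of coded evidence: ICD-9/10
#' diagnosis codes for primary pulmonary hypertension, CPT procedure codes for
#' right heart catheterization (RHC), and PAH-specific medications (generic
#' and brand names). The lexicon is data, not code: every list can be
#' overridden, and `read_lexicon()` loads one from a YAML file.
#'
#' Medication alias handling is configurable. With `collapse_aliases = FALSE`
#' (the default) every brand and generic name is its own screened variable, so
#' e.g. Flolan and epoprostenol accrue separate strength/persistence/durability
#' features; with `TRUE` aliases pool into their canonical generic.
#'
#' @param icd_codes character vector of ICD-9/10 codes for primary pulmonary
#'   hypertension.
#' @param cpt_codes character vector of RHC CPT code variants (93501 is the
#'   classic right-heart-catheterization code).
#' @param medications named list mapping each canonical generic name to a
#'   character vector of brand aliases (the generic itself is always an alias).
#' @param collapse_aliases logical; pool brand/generic mentions into the
#'   canonical generic variable?
#' @return an object of class `pah_lexicon`.
#' @export
#' @examples
#' lex <- default_lexicon()
#' lexicon_variables(lex)
pah_lexicon <- function(icd_codes, cpt_codes, medications,
                        collapse_aliases = FALSE) {
  icd_codes <- as.character(icd_codes)
  cpt_codes <- as.character(cpt_codes)
  if (length(icd_codes) == 0L) stop("lexicon: icd_codes must be non-empty")
  if (length(cpt_codes) == 0L) stop("lexicon: cpt_codes must be non-empty")
  if (length(medications) == 0L || is.null(names(medications)) ||
      any(names(medications) == "")) {
    stop("lexicon: medications must be a non-empty named list")
  }
  generic_names <- names(medications)
  medications <- lapply(seq_along(medications), function(i) {
    unique(c(generic_names[i], as.character(medications[[i]])))
  })
  names(medications) <- generic_names
  all_aliases <- tolower(unlist(medications))
  if (anyDuplicated(all_aliases)) {
    stop("lexicon: alias '", unlist(medications)[duplicated(all_aliases)][1L],
         "' maps to more than one generic")
  }
  structure(
    list(icd_codes = icd_codes, cpt_codes = cpt_codes,
         medications = medications, collapse_aliases = isTRUE(collapse_aliases)),
    class = "pah_lexicon"
  )
}

#' @rdname pah_lexicon
#' @export
default_lexicon <- function(collapse_aliases = FALSE) {
  meds <- list(
    epoprostenol = c("Flolan", "Veletri"),
    treprostinil = c("Remodulin", "Tyvaso", "Orenitram"),
    iloprost     = c("Ventavis"),
    bosentan     = c("Tracleer"),
    ambrisentan  = c("Letairis"),
    macitentan   = c("Opsumit"),
    sildenafil   = c("Revatio"),
    tadalafil    = c("Adcirca"),
    riociguat    = c("Adempas"),
    selexipag    = c("Uptravi")
  )
  pah_lexicon(
    icd_codes = c("416.0", "I27.0", "I27.2", "I27.20", "I27.21"),
    cpt_codes = c("93501", "93451", "93453", "93456", "93460", "93461"),
    medications = meds,
    collapse_aliases = collapse_aliases
  )
}

#' @rdname pah_lexicon
#' @param lexicon a `pah_lexicon`.
#' @export
lexicon_variables <- function(lexicon) {
  stopifnot(inherits(lexicon, "pah_lexicon"))
  med_vars <- if (lexicon$collapse_aliases) {
    names(lexicon$medications)
  } else {
    unlist(lexicon$medications, use.names = FALSE)
  }
  c(lexicon$icd_codes, lexicon$cpt_codes, med_vars)
}

# long lookup table mapping (vocabulary, lowercase code) -> screened variable
lexicon_match_table <- function(lexicon) {
  stopifnot(inherits(lexicon, "pah_lexicon"))
  icd <- data.table(
    vocabulary = "ICD", code_lower = tolower(lexicon$icd_codes),
    variable = lexicon$icd_codes, category = "icd"
  )
  cpt <- data.table(
    vocabulary = "CPT", code_lower = tolower(lexicon$cpt_codes),
    variable = lexicon$cpt_codes, category = "cpt"
  )
  med <- rbindlist(lapply(names(lexicon$medications), function(g) {
    aliases <- lexicon$medications[[g]]
    data.table(
      vocabulary = "MED", code_lower = tolower(aliases),
      variable = if (lexicon$collapse_aliases) g else aliases,
      category = "med"
    )
  }))
  rbindlist(list(icd, cpt, med))
}

#' Membership of each medication variable in a therapeutic class
#'
#' Used by the validation summary to report medication-class percentages
#' (endothelin receptor antagonists, guanylate-cyclase stimulators, PDE5
#' inhibitors, prostanoids) among predicted cases.
#'
#' @return named list of generic-name character vectors.
#' @export
default_med_classes <- function() {
  list(
    era        = c("bosentan", "ambrisentan", "macitentan"),
    gc_stim    = c("riociguat"),
    pde5       = c("sildenafil", "tadalafil"),
    prostanoid = c("epoprostenol", "treprostinil", "iloprost", "selexipag")
  )
}

# expand generic names of a class to all aliases (lowercased)
med_class_aliases <- function(lexicon, class_generics) {
  tolower(unlist(lexicon$medications[
    names(lexicon$medications) %in% class_generics], use.names = FALSE))
}

#' Default comorbidity code sets for the validation summary
#'
#' ICD codes used to count connective tissue disease (CTD) and congenital
#' heart disease (CHD) among predicted cases; the synthetic generator plants
#' the same codes.
#' @return named list of character vectors.
#' @export
default_comorbidity_codes <- function() {
  list(
    ctd = c("M34.9", "M32.9", "710.1", "710.0"),
    chd = c("Q21.1", "Q21.0", "745.5", "745.4")
  )
}

#' Read / write a lexicon as YAML
#'
#' @param path file path.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  x <- yaml::read_yaml(path)
  pah_lexicon(
    icd_codes = x$icd_codes, cpt_codes = x$cpt_codes,
    medications = x$medications,
    collapse_aliases = isTRUE(x$collapse_aliases)
  )
}

#' @rdname read_lexicon
#' @param lexicon a `pah_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "pah_lexicon"))
  meds <- lapply(names(lexicon$medications), function(g) {
    setdiff(lexicon$medications[[g]], g)
  })
  names(meds) <- names(lexicon$medications)
  yaml::write_yaml(
    list(icd_codes = lexicon$icd_codes, cpt_codes = lexicon$cpt_codes,
         medications = meds, collapse_aliases = lexicon$collapse_aliases),
    path
  )
  invisible(path)
}

#' @export
print.pah_lexicon <- function(x, ...) {
  cat("<pah_lexicon>\n")
  cat("  ICD codes: ", paste(x$icd_codes, collapse = ", "), "\n", sep = "")
  cat("  CPT codes: ", paste(x$cpt_codes, collapse = ", "), "\n", sep = "")
  cat("  medications: ", length(x$medications), " generics, ",
      length(unlist(x$medications)), " aliases (",
      if (x$collapse_aliases) "collapsed" else "separate", " variables)\n",
      sep = "")
  invisible(x)
}
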