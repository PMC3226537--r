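# Rule-based objective asthma diagnosis.
#
# The classifier implements a ten-row lookup table over four clinical
# fields.  For children treated with inhaled corticosteroids (ICS) in the
# three months before lung-function testing, symptomatology is not needed
# and the two objective tests decide; any positive test implies asthma and
# the doubly-negative cell is resolved by a configurable sensitivity rule
# (treatment may have normalised the tests).  For untreated children the
# recorded wheeze status is combined with reversibility and, where still
# needed, hyperreactivity.

#' Diagnostic profile of one child
#'
#' @param ics_use logical; inhaled corticosteroid use in the 3 months
#'   before the lung-function assessment. Must be `TRUE` or `FALSE`.
#' @param symptomatic logical or `NA`; wheeze in the 3 months before the
#'   measurements.
#' @param reversibility logical or `NA`; positive bronchodilator
#'   reversibility test.
#' @param hyperreactivity logical or `NA`; positive bronchial
#'   hyperreactivity (provocation) test.
#' @return An object of class `diagnostic_profile`.
#' @export
#' @examples
#' diagnostic_profile(FALSE, symptomatic = TRUE, reversibility = TRUE)
diagnostic_profile <- function(ics_use, symptomatic = NA,
                               reversibility = NA, hyperreactivity = NA) {
  as_flag <- function(x, field, allow_na = TRUE) {
    if (length(x) != 1L) abort("'%s' must be a single value", field)
    x <- as.logical(x)
    if (is.na(x) && !allow_na) abort("'%s' must be TRUE or FALSE", field)
    x
  }
  structure(
    list(
      ics_use         = as_flag(ics_use, "ics_use", allow_na = FALSE),
      symptomatic     = as_flag(symptomatic, "symptomatic"),
      reversibility   = as_flag(reversibility, "reversibility"),
      hyperreactivity = as_flag(hyperreactivity, "hyperreactivity")
    ),
    class = "diagnostic_profile"
  )
}

#' Diagnosis configuration
#'
#' Resolution of the treated, doubly test-negative cell of the diagnostic
#' table: a child on ICS whose reversibility and hyperreactivity tests are
#' both negative could be a well-controlled asthmatic or a non-asthmatic,
#' so the rule is run both ways as a sensitivity analysis.
#'
#' @param ics_pos_rev_neg_hyper_neg_rule `"negative"` (default,
#'   conservative) or `"positive"`.
#' @return An object of class `diagnosis_config`.
#' @export
diagnosis_config <- function(ics_pos_rev_neg_hyper_neg_rule = c("negative", "positive")) {
  rule <- match.arg(ics_pos_rev_neg_hyper_neg_rule)
  structure(list(ics_pos_rev_neg_hyper_neg_rule = rule),
            class = "diagnosis_config")
}

# Walk the lookup table.  Returns "positive"/"negative", or when
# `evaluability_only = TRUE` returns TRUE/FALSE for whether every field
# required along the lookup path is present.  Fields in "not needed"
# cells are deliberately never inspected.
walk_diagnosis_table <- function(profile, config, evaluability_only = FALSE) {
  need <- function(value, field) {
    if (is.na(value)) {
      if (evaluability_only) return(NA)  # sentinel: required field missing
      abort("profile is not evaluable: required field '%s' is missing", field)
    }
    value
  }
  out <- if (profile$ics_use) {
    # symptomatic not needed on the treated side
    rev <- need(profile$reversibility, "reversibility")
    if (evaluability_only && is.na(rev)) return(FALSE)
    hyper <- need(profile$hyperreactivity, "hyperreactivity")
    if (evaluability_only && is.na(hyper)) return(FALSE)
    if (rev || hyper) "positive" else config$ics_pos_rev_neg_hyper_neg_rule
  } else {
    symp <- need(profile$symptomatic, "symptomatic")
    if (evaluability_only && is.na(symp)) return(FALSE)
    rev <- need(profile$reversibility, "reversibility")
    if (evaluability_only && is.na(rev)) return(FALSE)
    if (symp) {
      if (rev) {
        "positive"                      # hyperreactivity not needed
      } else {
        hyper <- need(profile$hyperreactivity, "hyperreactivity")
        if (evaluability_only && is.na(hyper)) return(FALSE)
        if (hyper) "positive" else "negative"
      }
    } else {
      if (rev) {
        hyper <- need(profile$hyperreactivity, "hyperreactivity")
        if (evaluability_only && is.na(hyper)) return(FALSE)
        if (hyper) "positive" else "negative"
      } else {
        "negative"                      # hyperreactivity not needed
      }
    }
  }
  if (evaluability_only) TRUE else out
}

#' Classify asthma status from a diagnostic profile
#'
#' Applies the objective diagnosis lookup table. Fields whose table cell
#' is "not needed" for the matched row may be missing and are never read.
#'
#' @param profile a [diagnostic_profile()].
#' @param config a [diagnosis_config()].
#' @return `"positive"` or `"negative"`.
#' @seealso [is_evaluable()]
#' @export
#' @examples
#' cfg <- diagnosis_config()
#' classify_asthma(diagnostic_profile(TRUE, reversibility = TRUE,
#'                                    hyperreactivity = FALSE), cfg)
classify_asthma <- function(profile, config = diagnosis_config()) {
  stopifnot(inherits(profile, "diagnostic_profile"),
            inherits(config, "diagnosis_config"))
  walk_diagnosis_table(profile, config)
}

#' Is a diagnostic profile evaluable?
#'
#' `TRUE` iff every field required along the profile's lookup path in the
#' diagnosis table is non-missing, honouring "not needed" cells. Only
#' evaluable records enter the modelling.
#'
#' @param profile a [diagnostic_profile()].
#' @return logical scalar.
#' @export
is_evaluable <- function(profile) {
  stopifnot(inherits(profile, "diagnostic_profile"))
  walk_diagnosis_table(profile, diagnosis_config(), evaluability_only = TRUE)
}

# Row-wise wrappers over a cohort data frame -------------------------------

profile_from_row <- function(row) {
  diagnostic_profile(row$ics_use, row$symptomatic,
                     row$reversibility, row$hyperreactivity)
}

# Vectorized equivalents of is_evaluable / classify_asthma over cohort
# rows (the scalar table-walkers above are the reference; agreement over
# the full input space is asserted in the test suite).

# logical vector: evaluability of each cohort row
cohort_evaluable <- function(cohort) {
  if (nrow(cohort) == 0L) return(logical(0))
  ics <- as.logical(cohort$ics_use)
  s <- as.logical(cohort$symptomatic)
  r <- as.logical(cohort$reversibility)
  h <- as.logical(cohort$hyperreactivity)
  have <- Negate(is.na)
  # treated: both tests required; untreated: symptom and reversibility
  # required, hyperreactivity only off the "not needed" rows
  ifelse(ics,
         have(r) & have(h),
         have(s) & have(r) & ((s & r) | (!s & !r) | have(h)))
}

# character vector of "positive"/"negative"; rows must be evaluable
cohort_diagnose <- function(cohort, config = diagnosis_config()) {
  if (nrow(cohort) == 0L) return(character(0))
  ics <- as.logical(cohort$ics_use)
  s <- as.logical(cohort$symptomatic)
  r <- as.logical(cohort$reversibility)
  h <- as.logical(cohort$hyperreactivity)
  rule_pos <- config$ics_pos_rev_neg_hyper_neg_rule == "positive"
  pos <- ifelse(ics,
                ifelse(r | h, TRUE, rule_pos),
                ifelse(s,
                       ifelse(r, TRUE, h),     # hyper not needed when rev+
                       ifelse(r, h, FALSE)))   # hyper not needed when rev-
  if (anyNA(pos)) {
    abort("row %d is not evaluable", which(is.na(pos))[1])
  }
  ifelse(pos, "positive", "negative")
}
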