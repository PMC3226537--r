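# Cohort preparation: evaluability filter, per-protocol strategy
# grouping, and the current-situation population mixture.
#
# Children enter on first-degree familial asthma history (PFH positive,
# NFH negative).  Because the original trials randomised only to
# intervention vs control, the unifaceted/multifaceted contrast is
# derived per protocol from observed compliance: adherence to measures
# against both airborne and food allergen triggers is multifaceted,
# exactly one is unifaceted, neither is control.  The usual-care
# comparator ("current situation") is a 20%/80% mixture of PFH controls
# and NFH children, the ratio of the two strata in the general
# population.

#' Filter a cohort to evaluable records
#'
#' Drops records whose diagnostic profile cannot be classified because a
#' field required along its lookup path is missing.
#'
#' @param cohort a cohort data frame (see [read_cohort()] for the schema).
#' @return A list with `kept` (the evaluable subset) and `n_excluded`.
#' @export
filter_evaluable <- function(cohort) {
  ok <- cohort_evaluable(cohort)
  list(kept = cohort[ok, , drop = FALSE],
       n_excluded = sum(!ok))
}

#' Per-protocol strategy group of each record
#'
#' PFH records are grouped by compliance: both measures adhered to is
#' `multifaceted`, exactly one is `unifaceted`, neither is `pfh_control`.
#' NFH records form the `nfh` stratum. Assignment is immutable: children
#' do not shift between prevention categories.
#'
#' @param cohort a cohort data frame.
#' @return Character vector of group labels, one per record.
#' @export
assign_group <- function(cohort) {
  cohort_groups(cohort)
}

cohort_groups <- function(cohort) {
  n <- nrow(cohort)
  if (n == 0L) return(character(0))
  out <- character(n)
  is_nfh <- cohort$family_history == "NFH"
  out[is_nfh] <- "nfh"
  pfh <- which(!is_nfh)
  if (length(pfh)) {
    air <- cohort$airborne_compliant[pfh]
    food <- cohort$food_compliant[pfh]
    if (anyNA(air) || anyNA(food)) {
      bad <- pfh[is.na(air) | is.na(food)][1]
      abort("PFH record '%s' has undefined compliance flags",
            cohort$id[bad])
    }
    out[pfh] <- ifelse(air & food, "multifaceted",
                       ifelse(air | food, "unifaceted", "pfh_control"))
  }
  out
}

#' Record counts per strategy group
#'
#' @param cohort a cohort data frame.
#' @return Named integer vector over the four groups (zero where absent);
#'   counts partition the cohort.
#' @export
group_counts <- function(cohort) {
  grp <- factor(cohort_groups(cohort), levels = strategy_groups())
  tab <- table(grp)
  stats::setNames(as.integer(tab), names(tab))
}

#' Mixture weights for the current-situation comparator
#'
#' @param w_pfh proportion of the general population with a positive
#'   familial history, default 0.20; the NFH weight is its complement.
#' @return An object of class `mixture_weights`.
#' @export
mixture_weights <- function(w_pfh = 0.20) {
  check_prob(w_pfh, "w_pfh")
  structure(list(w_pfh = w_pfh, w_nfh = 1 - w_pfh),
            class = "mixture_weights")
}

#' Current-situation expectation as a population mixture
#'
#' Combines the PFH-control and NFH strategy expectations with the
#' population prevalence weights. By linearity of expectation this equals
#' record-level weighted pooling.
#'
#' @param exp_pfh_control,exp_nfh [strategy_expectation()] objects.
#' @param weights a [mixture_weights()].
#' @return A [strategy_expectation()] labelled `"current"`.
#' @export
current_mixture <- function(exp_pfh_control, exp_nfh,
                            weights = mixture_weights()) {
  stopifnot(inherits(exp_pfh_control, "strategy_expectation"),
            inherits(exp_nfh, "strategy_expectation"),
            inherits(weights, "mixture_weights"))
  strategy_expectation(
    strategy = "current",
    expected_cost = weights$w_pfh * exp_pfh_control$expected_cost +
      weights$w_nfh * exp_nfh$expected_cost,
    p_asthma_avoided = weights$w_pfh * exp_pfh_control$p_asthma_avoided +
      weights$w_nfh * exp_nfh$p_asthma_avoided,
    n = sum(exp_pfh_control$n, exp_nfh$n, na.rm = TRUE)
  )
}
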