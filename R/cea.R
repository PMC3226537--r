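# Incremental cost-effectiveness analysis: ICER with dominance
# classification, the efficient frontier, and a net-monetary-benefit
# sweep over willingness-to-pay thresholds (EUR per asthma case
# avoided).

# coerce a list of strategy_expectation (or a data frame) to the
# canonical expectation table
as_expectation_table <- function(expectations) {
  if (is.data.frame(expectations)) {
    need <- c("strategy", "expected_cost", "p_asthma_avoided")
    missing_cols <- setdiff(need, names(expectations))
    if (length(missing_cols)) {
      abort("expectation table is missing column(s): %s",
            paste(missing_cols, collapse = ", "))
    }
    df <- expectations
    if (is.null(df$n)) df$n <- NA_integer_
    return(df[c(need, "n")])
  }
  if (inherits(expectations, "strategy_expectation")) {
    expectations <- list(expectations)
  }
  do.call(rbind, lapply(expectations, function(e) {
    stopifnot(inherits(e, "strategy_expectation"))
    data.frame(strategy = e$strategy, expected_cost = e$expected_cost,
               p_asthma_avoided = e$p_asthma_avoided, n = e$n,
               stringsAsFactors = FALSE)
  }))
}

classify_pair <- function(delta_cost, delta_effect) {
  if (delta_cost == 0 && delta_effect == 0) return("equivalent")
  if (delta_cost <= 0 && delta_effect >= 0) return("dominant")
  if (delta_cost >= 0 && delta_effect <= 0) return("strongly_dominated")
  "icer"
}

#' Incremental cost-effectiveness analysis against a reference strategy
#'
#' For each non-reference strategy, the incremental cost `delta_cost`,
#' incremental effect `delta_effect` (probability of asthma avoidance)
#' and either the ICER `delta_cost / delta_effect` or a dominance label:
#' `strongly_dominated` (costlier and no more effective than the
#' reference), `dominant` (cheaper and at least as effective),
#' `equivalent` (identical). Dominance quadrants never report a signed
#' ratio. The headline ICER is also given rounded to the nearest EUR
#' 1,000 (`icer_rounded_1000`).
#'
#' @param expectations list of [strategy_expectation()]s or a data frame
#'   with columns `strategy`, `expected_cost`, `p_asthma_avoided`.
#' @param reference label of the reference strategy.
#' @return Data frame with one row per comparator.
#' @export
#' @examples
#' exps <- list(
#'   strategy_expectation("multifaceted", 539.49, 0.93191),
#'   strategy_expectation("unifaceted", 445.19, 0.92610))
#' incremental_analysis(exps, reference = "unifaceted")
incremental_analysis <- function(expectations, reference) {
  tab <- as_expectation_table(expectations)
  if (anyDuplicated(tab$strategy)) {
    abort("duplicate strategy label(s): %s",
          paste(unique(tab$strategy[duplicated(tab$strategy)]), collapse = ", "))
  }
  if (nrow(tab) < 2L) abort("need at least two strategies")
  if (!reference %in% tab$strategy) {
    abort("reference strategy '%s' not present", reference)
  }
  ref <- tab[tab$strategy == reference, ]
  cmp <- tab[tab$strategy != reference, ]
  out <- lapply(seq_len(nrow(cmp)), function(i) {
    dc <- cmp$expected_cost[i] - ref$expected_cost
    de <- cmp$p_asthma_avoided[i] - ref$p_asthma_avoided
    lab <- classify_pair(dc, de)
    icer <- if (lab == "icer") dc / de else NA_real_
    data.frame(comparator = cmp$strategy[i], reference = reference,
               delta_cost = dc, delta_effect = de,
               icer = icer,
               icer_rounded_1000 = if (is.na(icer)) NA_real_ else
                 round_half_up(icer / 1000, 0) * 1000,
               dominance = if (lab == "icer") NA_character_ else lab,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cost-effectiveness efficient frontier
#'
#' Sorts strategies by expected cost, removes strongly dominated ones
#' (weakly costlier and weakly less effective than some other strategy,
#' at least one strictly), then iteratively removes extendedly dominated
#' ones (a higher incremental ICER than the next more effective option).
#' Strategies with equal consecutive ICERs (collinear) are all retained.
#'
#' @param expectations as in [incremental_analysis()].
#' @return Data frame of all strategies with columns `strategy`,
#'   `expected_cost`, `p_asthma_avoided`, `status`
#'   (`on_frontier`/`strongly_dominated`/`extendedly_dominated`) and
#'   `icer` (vs the previous frontier member; `NA` for the cheapest).
#' @export
efficient_frontier <- function(expectations) {
  tab <- as_expectation_table(expectations)
  if (nrow(tab) == 0L) abort("need at least one strategy")
  tab <- tab[order(tab$expected_cost, -tab$p_asthma_avoided), ]
  tab$status <- "on_frontier"
  tab$icer <- NA_real_
  n <- nrow(tab)
  # strong dominance (weak inequalities, one strict)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dc <- tab$expected_cost[i] - tab$expected_cost[j]
      de <- tab$p_asthma_avoided[i] - tab$p_asthma_avoided[j]
      if (dc >= 0 && de <= 0 && (dc > 0 || de < 0)) {
        tab$status[i] <- "strongly_dominated"
        break
      }
    }
  }
  # extended dominance: drop members whose ICER exceeds the next one
  repeat {
    idx <- which(tab$status == "on_frontier")
    if (length(idx) < 3L) break
    icers <- diff(tab$expected_cost[idx]) / diff(tab$p_asthma_avoided[idx])
    bad <- which(utils::head(icers, -1) > utils::tail(icers, -1))
    if (!length(bad)) break
    tab$status[idx[bad[1] + 1L]] <- "extendedly_dominated"
  }
  idx <- which(tab$status == "on_frontier")
  if (length(idx) > 1L) {
    tab$icer[idx[-1]] <- diff(tab$expected_cost[idx]) /
      diff(tab$p_asthma_avoided[idx])
  }
  rownames(tab) <- NULL
  tab
}

#' Net monetary benefit
#'
#' `lambda * p_asthma_avoided - expected_cost` at willingness to pay
#' `lambda` (EUR per asthma case avoided).
#'
#' @param expectation a [strategy_expectation()] (or anything with
#'   `expected_cost` and `p_asthma_avoided` fields).
#' @param lambda non-negative willingness to pay; may be a vector.
#' @return EUR net benefit, same length as `lambda`.
#' @export
net_benefit <- function(expectation, lambda) {
  if (any(lambda < 0)) abort("'lambda' must be non-negative")
  lambda * expectation$p_asthma_avoided - expectation$expected_cost
}

#' Net-benefit threshold sweep
#'
#' Evaluates every strategy's net monetary benefit on a willingness-to-pay
#' grid and records the optimum per grid point. Ties are broken in favour
#' of the lower-cost strategy (then alphabetically, for determinism).
#'
#' @param expectations as in [incremental_analysis()].
#' @param lambda_min,lambda_max grid endpoints in EUR per asthma case
#'   avoided (defaults 0 and 70,000).
#' @param step grid step (default 1,000), > 0.
#' @return An object of class `threshold_curve`: list with `lambda`
#'   (grid), `net_benefit` (strategies x grid matrix) and `optimal`
#'   (strategy label per grid point).
#' @export
threshold_sweep <- function(expectations, lambda_min = 0,
                            lambda_max = 70000, step = 1000) {
  if (step <= 0) abort("'step' must be positive")
  if (lambda_min > lambda_max) abort("'lambda_min' must be <= 'lambda_max'")
  if (lambda_min < 0) abort("'lambda_min' must be non-negative")
  tab <- as_expectation_table(expectations)
  if (anyDuplicated(tab$strategy)) abort("duplicate strategy labels")
  grid <- seq(lambda_min, lambda_max, by = step)
  nmb <- vapply(grid, function(l) l * tab$p_asthma_avoided - tab$expected_cost,
                numeric(nrow(tab)))
  nmb <- matrix(nmb, nrow = nrow(tab),
                dimnames = list(tab$strategy, format(grid, scientific = FALSE,
                                                     trim = TRUE)))
  ord <- order(tab$expected_cost, tab$strategy)  # tie-break preference
  optimal <- apply(nmb, 2, function(col) {
    best <- max(col)
    cand <- which(col >= best - 1e-9 * max(1, abs(best)))
    tab$strategy[intersect(ord, cand)[1]]
  })
  structure(list(lambda = grid, net_benefit = nmb,
                 optimal = unname(optimal)),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf("<threshold_curve> %d strategies over lambda %s..%s\n",
              nrow(x$net_benefit), format(min(x$lambda), big.mark = ","),
              format(max(x$lambda), big.mark = ",")))
  tab <- table(x$optimal)
  for (s in names(tab)) {
    cat(sprintf("  optimal at %d/%d grid points: %s\n",
                tab[[s]], length(x$lambda), s))
  }
  invisible(x)
}

#' @export
as.data.frame.threshold_curve <- function(x, ...) {
  data.frame(lambda = rep(x$lambda, each = nrow(x$net_benefit)),
             strategy = rep(rownames(x$net_benefit), times = length(x$lambda)),
             net_benefit = as.vector(x$net_benefit),
             stringsAsFactors = FALSE)
}
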