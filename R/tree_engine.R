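# Decision-tree engine: empirical branch probabilities, tree
# construction per strategy, and fold-back (roll-back) of expected costs
# and outcomes.
#
# The per-strategy chance tree is fixed:
#
#   symptomatic? --yes--> pharmacotherapy? --ICS--> diagnosis +/-
#                                         --none--> diagnosis +/-
#                --no---> diagnosis +/-
#
# Children either remain healthy or manifest asthma signs and symptoms;
# symptomatic children may or may not receive pharmacotherapy (modelled
# as the ICS flag, which in turn feeds the diagnosis rule); the terminal
# outcome is a positive or negative objective asthma diagnosis.
# Asymptomatic children proceed directly to diagnosis — around age six a
# large share of children with asthma are symptom-free but test-positive.

#' Strategy expectation
#'
#' The folded-back value of one strategy: expected per-child cost and the
#' probability of avoiding an asthma diagnosis.
#'
#' @param strategy strategy label.
#' @param expected_cost EUR, >= 0.
#' @param p_asthma_avoided probability in `[0, 1]`.
#' @param n record count backing the estimate (`NA` for analytic values).
#' @return An object of class `strategy_expectation`.
#' @export
strategy_expectation <- function(strategy, expected_cost, p_asthma_avoided,
                                 n = NA_integer_) {
  check_nonneg(expected_cost, "expected_cost")
  check_prob(p_asthma_avoided, "p_asthma_avoided")
  structure(list(strategy = strategy,
                 expected_cost = expected_cost,
                 p_asthma_avoided = p_asthma_avoided,
                 n = n),
            class = "strategy_expectation")
}

#' @export
print.strategy_expectation <- function(x, ...) {
  cat(sprintf("<%s>  E[cost] = %.2f EUR  P(asthma avoided) = %.5f  (n = %s)\n",
              x$strategy, x$expected_cost, x$p_asthma_avoided,
              ifelse(is.na(x$n), "analytic", x$n)))
  invisible(x)
}

# Tree nodes ---------------------------------------------------------------

#' Terminal (leaf) node
#'
#' @param cost terminal payoff in EUR.
#' @param asthma logical; `TRUE` for a positive asthma diagnosis.
#' @param label node label.
#' @return A `tree_node` of kind `"terminal"`.
#' @export
terminal_node <- function(cost, asthma, label = "terminal") {
  check_nonneg(cost, "cost")
  structure(list(kind = "terminal", label = label,
                 payoff = list(cost = cost, asthma = isTRUE(asthma))),
            class = "tree_node")
}

#' Chance node
#'
#' @param label node label.
#' @param branches list of branches, each `list(label =, prob =, node =)`;
#'   probabilities must lie in `[0, 1]` and sum to 1.
#' @return A `tree_node` of kind `"chance"`.
#' @export
chance_node <- function(label, branches) {
  probs <- vapply(branches, `[[`, numeric(1), "prob")
  check_prob(probs, paste0("branch probabilities of '", label, "'"))
  if (abs(sum(probs) - 1) > 1e-9) {
    abort("branch probabilities of node '%s' sum to %.12f, not 1",
          label, sum(probs))
  }
  structure(list(kind = "chance", label = label, branches = branches),
            class = "tree_node")
}

#' Decision node
#'
#' Carries no probabilities; alternatives are folded back separately and
#' compared downstream by the incremental analysis.
#'
#' @param label node label.
#' @param alternatives named list of child `tree_node`s.
#' @return A `tree_node` of kind `"decision"`.
#' @export
decision_node <- function(label, alternatives) {
  structure(list(kind = "decision", label = label,
                 alternatives = alternatives),
            class = "tree_node")
}

#' Empirical branch probability
#'
#' The ratio of one situation's count over its sum with the complement.
#' An empty cell (both counts zero) is resolved by the configured policy:
#' `"additive"` smoothing adds a pseudo-count per branch (default 0.5,
#' giving 0.5 for an empty pair), `"strict"` errors, `"collapse"` returns
#' `NA` so the caller can drop the node.
#'
#' @param n_event,n_complement non-negative counts.
#' @param policy empty-cell policy.
#' @param pseudocount additive pseudo-count per branch.
#' @param branch branch label used in error messages.
#' @return Probability of the event, or `NA` under `"collapse"` on an
#'   empty cell.
#' @export
#' @examples
#' estimate_branch_probability(3, 1)               # 0.75
#' estimate_branch_probability(0, 0)               # 0.5 (additive)
estimate_branch_probability <- function(n_event, n_complement,
                                        policy = c("additive", "strict", "collapse"),
                                        pseudocount = 0.5,
                                        branch = "branch") {
  policy <- match.arg(policy)
  n_event <- check_count(n_event, "n_event")
  n_complement <- check_count(n_complement, "n_complement")
  total <- n_event + n_complement
  if (total > 0L) return(n_event / total)
  switch(policy,
         strict = abort("empty cell at '%s': no observations on either branch",
                        branch),
         collapse = NA_real_,
         additive = (n_event + pseudocount) / (total + 2 * pseudocount))
}

# Tree construction --------------------------------------------------------

# Effective path fields: a child is on the treated branch iff ICS was
# used; ICS implies symptomatic (pharmacotherapy sits on the symptomatic
# branch), so the symptomatic branch is ICS | recorded wheeze.
path_fields <- function(cohort) {
  treated <- as.logical(cohort$ics_use)
  symptomatic <- treated | (!is.na(cohort$symptomatic) & cohort$symptomatic)
  list(treated = treated, symptomatic = symptomatic)
}

# Diagnosis chance node over a subset of records. `fallback_cost` is the
# mean cost one level up, used for branches reachable only through a
# smoothed empty cell.
diagnosis_subtree <- function(diag, costs, label, policy, pseudocount,
                              fallback_cost, events) {
  pos <- diag == "positive"
  p_pos <- estimate_branch_probability(sum(pos), sum(!pos), policy,
                                       pseudocount, branch = label)
  if (length(diag) == 0L) events$push(label)
  mean_or <- function(x, fb) if (length(x)) mean(x) else fb
  if (is.na(p_pos)) return(NULL)  # collapse: caller prunes
  branches <- list(
    list(label = "asthma_positive", prob = p_pos,
         node = terminal_node(mean_or(costs[pos], fallback_cost), TRUE,
                              paste0(label, "/positive"))),
    list(label = "asthma_negative", prob = 1 - p_pos,
         node = terminal_node(mean_or(costs[!pos], fallback_cost), FALSE,
                              paste0(label, "/negative")))
  )
  # prune exact zero-probability branches so fold-back never visits an
  # unobserved subtree
  branches <- Filter(function(b) b$prob > 0, branches)
  if (length(branches) == 1L) branches[[1]]$prob <- 1
  chance_node(label, branches)
}

#' Build the chance tree of one strategy group
#'
#' Estimates every branch probability empirically from the grouped,
#' evaluable records and attaches mean observed per-child costs as
#' terminal payoffs.
#'
#' @param cohort evaluable records of a single strategy group.
#' @param price_table a [unit_price_table()].
#' @param config a [diagnosis_config()].
#' @param policy empty-cell policy, see [estimate_branch_probability()].
#' @param pseudocount additive smoothing pseudo-count.
#' @param include_intervention count intervention-category items in the
#'   per-child costs (defaults to `TRUE` for prevention groups).
#' @return A `tree_node`; attribute `empty_cells` lists the labels of
#'   chance nodes that required the empty-cell policy.
#' @export
build_strategy_tree <- function(cohort, price_table,
                                config = diagnosis_config(),
                                policy = c("additive", "strict", "collapse"),
                                pseudocount = 0.5,
                                include_intervention = NULL) {
  policy <- match.arg(policy)
  if (nrow(cohort) == 0L) abort("cannot build a strategy tree from no records")
  grp <- unique(cohort_groups(cohort))
  if (length(grp) != 1L) {
    abort("records span several strategy groups: %s",
          paste(grp, collapse = ", "))
  }
  if (is.null(include_intervention)) {
    include_intervention <- grp %in% c("multifaceted", "unifaceted")
  }
  costs <- costs_for(cohort, price_table, include_intervention)
  diag <- cohort_diagnose(cohort, config)
  pf <- path_fields(cohort)

  events <- local({
    seen <- character(0)
    list(push = function(x) seen <<- c(seen, x), get = function() seen)
  })
  root_label <- grp

  symp <- pf$symptomatic
  p_symp <- estimate_branch_probability(sum(symp), sum(!symp), policy,
                                        pseudocount,
                                        branch = paste0(root_label, "/symptomatic"))
  group_mean <- mean(costs)

  # symptomatic side: pharmacotherapy chance node. Zero-probability
  # branches are pruned before their subtrees are built, so the
  # empty-cell policy only fires for cells that are actually reachable
  # (positive probability but no backing records, i.e. downstream of a
  # smoothed empty cell).
  symp_subtree <- function() {
    idx <- symp
    treated <- pf$treated[idx]
    lbl <- paste0(root_label, "/symptomatic/pharmacotherapy")
    p_rx <- estimate_branch_probability(sum(treated), sum(!treated), policy,
                                        pseudocount, branch = lbl)
    if (sum(idx) == 0L) events$push(lbl)
    if (is.na(p_rx)) return(NULL)
    side_mean <- if (any(idx)) mean(costs[idx]) else group_mean
    mk <- function(sel, name) {
      diagnosis_subtree(diag[idx][sel], costs[idx][sel],
                        paste0(lbl, "/", name, "/diagnosis"),
                        policy, pseudocount, side_mean, events)
    }
    branches <- list()
    if (p_rx > 0) {
      branches <- c(branches, list(list(label = "ics", prob = p_rx,
                                        node = mk(treated, "ics"))))
    }
    if (p_rx < 1) {
      branches <- c(branches, list(list(label = "no_pharmacotherapy",
                                        prob = 1 - p_rx,
                                        node = mk(!treated, "none"))))
    }
    branches <- Filter(function(b) !is.null(b$node), branches)
    if (length(branches) == 0L) return(NULL)
    if (length(branches) == 1L) branches[[1]]$prob <- 1
    chance_node(lbl, branches)
  }

  branches <- list()
  if (!is.na(p_symp) && p_symp > 0) {
    branches <- c(branches, list(list(label = "symptomatic", prob = p_symp,
                                      node = symp_subtree())))
  }
  if (!is.na(p_symp) && p_symp < 1) {
    branches <- c(branches, list(list(
      label = "asymptomatic", prob = 1 - p_symp,
      node = diagnosis_subtree(diag[!symp], costs[!symp],
                               paste0(root_label, "/asymptomatic/diagnosis"),
                               policy, pseudocount, group_mean, events))))
  }
  branches <- Filter(function(b) !is.null(b$node), branches)
  if (length(branches) == 0L) abort("all branches collapsed for '%s'", grp)
  if (length(branches) == 1L) branches[[1]]$prob <- 1
  tree <- chance_node(paste0(root_label, "/symptomatic?"), branches)
  attr(tree, "empty_cells") <- events$get()
  tree
}

# Fold-back and the enumeration oracle -------------------------------------

#' Fold back a chance tree
#'
#' Leaf-to-root probability-weighted aggregation: expected cost and the
#' probability of a negative asthma diagnosis ("asthma avoided").
#'
#' @param tree a `tree_node` containing no decision nodes.
#' @return List with `expected_cost` and `p_asthma_avoided`.
#' @export
fold_back <- function(tree) {
  stopifnot(inherits(tree, "tree_node"))
  rec <- function(node) {
    switch(node$kind,
      terminal = c(cost = node$payoff$cost,
                   avoid = if (node$payoff$asthma) 0 else 1),
      chance = {
        probs <- vapply(node$branches, `[[`, numeric(1), "prob")
        if (abs(sum(probs) - 1) > 1e-9) {
          abort("branch probabilities of node '%s' sum to %.12f, not 1",
                node$label, sum(probs))
        }
        vals <- lapply(node$branches, function(b) rec(b$node))
        Reduce(`+`, Map(function(p, v) p * v, probs, vals))
      },
      decision = abort("unresolved decision node '%s'; fold strategies separately",
                       node$label)
    )
  }
  out <- rec(tree)
  list(expected_cost = unname(out["cost"]),
       p_asthma_avoided = unname(out["avoid"]))
}

#' Enumerate root-to-leaf paths
#'
#' Brute-force oracle for [fold_back()]: path probabilities multiply
#' along each path and sum to 1 over all paths.
#'
#' @param tree a `tree_node` containing no decision nodes.
#' @return Data frame with columns `probability`, `cost`, `asthma`.
#' @export
enumerate_paths <- function(tree) {
  stopifnot(inherits(tree, "tree_node"))
  rows <- list()
  rec <- function(node, p) {
    if (node$kind == "terminal") {
      rows[[length(rows) + 1L]] <<- data.frame(
        probability = p, cost = node$payoff$cost, asthma = node$payoff$asthma)
    } else if (node$kind == "chance") {
      for (b in node$branches) rec(b$node, p * b$prob)
    } else {
      abort("unresolved decision node '%s'", node$label)
    }
  }
  rec(tree, 1)
  do.call(rbind, rows)
}

#' Fold a strategy tree into a strategy expectation
#'
#' @param tree a strategy chance tree.
#' @param strategy strategy label.
#' @param n backing record count.
#' @return A [strategy_expectation()].
#' @export
fold_strategy <- function(tree, strategy, n = NA_integer_) {
  fb <- fold_back(tree)
  strategy_expectation(strategy, fb$expected_cost, fb$p_asthma_avoided, n)
}

# JSON serialization -------------------------------------------------------

tree_to_list <- function(node) {
  switch(node$kind,
    terminal = list(kind = "terminal", label = node$label,
                    payoff = list(cost = node$payoff$cost,
                                  asthma = node$payoff$asthma)),
    chance = list(kind = "chance", label = node$label,
                  branches = lapply(node$branches, function(b) {
                    list(label = b$label, probability = b$prob,
                         node = tree_to_list(b$node))
                  })),
    decision = list(kind = "decision", label = node$label,
                    alternatives = lapply(node$alternatives, tree_to_list))
  )
}

#' Serialize a tree to JSON
#'
#' @param tree a `tree_node`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  js <- jsonlite::toJSON(tree_to_list(tree), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Rebuild a tree from its JSON serialization
#'
#' @param json JSON string or file path.
#' @return A `tree_node`.
#' @export
tree_from_json <- function(json) {
  from_list <- function(x) {
    switch(x$kind,
      terminal = terminal_node(x$payoff$cost, isTRUE(x$payoff$asthma), x$label),
      chance = chance_node(x$label, lapply(x$branches, function(b) {
        list(label = b$label, prob = b$probability, node = from_list(b$node))
      })),
      decision = decision_node(x$label, lapply(x$alternatives, from_list))
    )
  }
  from_list(jsonlite::fromJSON(json, simplifyVector = FALSE))
}
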