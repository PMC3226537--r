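# Synthetic cohort generator.
#
# The individual-level trial data behind the analysis are not deposited,
# so the pipeline is exercised on synthetic cohorts with the same
# statistical structure: two familial-risk strata (PFH/NFH), per-protocol
# strategy groups sized like the published ones (259/53/12 PFH plus an
# NFH stratum), per-group probabilities of symptoms, pharmacotherapy and
# test outcomes, Poisson resource-use counts, and independent per-field
# missingness on the diagnostic measurements.  A closed-form expectation
# oracle over the finite outcome space backs parameter-recovery and
# fold-back tests.  All default rates are placeholders, not estimates of
# the trial.

#' Generator parameters
#'
#' Each probability argument is given per strategy group. Test-outcome
#' probabilities may be conditioned on symptomatic status by supplying a
#' length-2 vector `c(symptomatic =, asymptomatic =)` instead of a
#' scalar; the default is independence.
#'
#' @param n named counts per group
#'   (`multifaceted`, `unifaceted`, `pfh_control`, `nfh`).
#' @param p_symptomatic per-group probability of wheeze in the recall
#'   window.
#' @param p_ics_given_symptomatic per-group probability that a
#'   symptomatic child receives ICS pharmacotherapy (asymptomatic
#'   children are never treated; the treated branch of the tree is the
#'   ICS flag).
#' @param p_reversibility_pos,p_hyperreactivity_pos per-group probability
#'   of a positive test; scalar or `c(symptomatic =, asymptomatic =)`.
#' @param resource_rates named list: group -> named vector of Poisson
#'   means per cost item; a single named vector is recycled to all
#'   groups.
#' @param missingness per-field missingness probabilities, named
#'   `symptomatic`, `reversibility`, `hyperreactivity`.
#' @param seed master integer seed; per-group substreams are derived from
#'   it (see Details).
#'
#' @details One master seed drives the whole cohort. Each group draws
#' from its own substream seeded with
#' `(seed * 48271 + group_index) mod (2^31 - 1)`, so a single group can
#' be regenerated without simulating the others.
#'
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n = c(multifaceted = 259, unifaceted = 53,
                                   pfh_control = 12, nfh = 500),
                             p_symptomatic = c(multifaceted = 0.22,
                                               unifaceted = 0.26,
                                               pfh_control = 0.30,
                                               nfh = 0.15),
                             p_ics_given_symptomatic = c(multifaceted = 0.35,
                                                         unifaceted = 0.35,
                                                         pfh_control = 0.40,
                                                         nfh = 0.25),
                             p_reversibility_pos = list(
                               multifaceted = c(symptomatic = 0.25, asymptomatic = 0.05),
                               unifaceted   = c(symptomatic = 0.28, asymptomatic = 0.06),
                               pfh_control  = c(symptomatic = 0.30, asymptomatic = 0.07),
                               nfh          = c(symptomatic = 0.20, asymptomatic = 0.03)),
                             p_hyperreactivity_pos = list(
                               multifaceted = c(symptomatic = 0.30, asymptomatic = 0.06),
                               unifaceted   = c(symptomatic = 0.33, asymptomatic = 0.07),
                               pfh_control  = c(symptomatic = 0.35, asymptomatic = 0.08),
                               nfh          = c(symptomatic = 0.22, asymptomatic = 0.04)),
                             resource_rates = default_resource_rates(),
                             missingness = c(symptomatic = 0.05,
                                             reversibility = 0.10,
                                             hyperreactivity = 0.10),
                             seed = 20090101L) {
  groups <- strategy_groups()

  norm_per_group <- function(x, field) {
    if (!is.list(x)) x <- as.list(x)
    if (is.null(names(x)) && length(x) == length(groups)) names(x) <- groups
    missing_g <- setdiff(groups, names(x))
    if (length(missing_g)) {
      abort("'%s' must be given for group(s): %s", field,
            paste(missing_g, collapse = ", "))
    }
    x[groups]
  }
  norm_cond <- function(x, field) {
    x <- norm_per_group(x, field)
    lapply(stats::setNames(groups, groups), function(g) {
      v <- unlist(x[[g]])
      if (length(v) == 1L) v <- c(symptomatic = unname(v), asymptomatic = unname(v))
      if (!all(c("symptomatic", "asymptomatic") %in% names(v))) {
        abort("'%s[%s]' must be a scalar or c(symptomatic=, asymptomatic=)",
              field, g)
      }
      check_prob(v, sprintf("%s[%s]", field, g))
      v[c("symptomatic", "asymptomatic")]
    })
  }

  n <- unlist(norm_per_group(n, "n"))
  for (g in groups) check_count(n[[g]], sprintf("n[%s]", g))
  p_symptomatic <- unlist(norm_per_group(p_symptomatic, "p_symptomatic"))
  check_prob(p_symptomatic, "p_symptomatic")
  p_ics <- unlist(norm_per_group(p_ics_given_symptomatic,
                                 "p_ics_given_symptomatic"))
  check_prob(p_ics, "p_ics_given_symptomatic")
  p_rev <- norm_cond(p_reversibility_pos, "p_reversibility_pos")
  p_hyper <- norm_cond(p_hyperreactivity_pos, "p_hyperreactivity_pos")

  if (is.null(names(resource_rates))) {
    abort("'resource_rates' must be a named list or named vector")
  }
  if (!is.list(resource_rates)) resource_rates <- as.list(resource_rates)
  if (!any(names(resource_rates) %in% groups)) {
    resource_rates <- stats::setNames(
      rep(list(unlist(resource_rates)), length(groups)), groups)
  }
  resource_rates <- norm_per_group(resource_rates, "resource_rates")
  for (g in groups) {
    rr <- unlist(resource_rates[[g]])
    if (length(rr) && is.null(names(rr))) {
      abort("'resource_rates[%s]' must be named by cost item", g)
    }
    check_nonneg(rr, sprintf("resource_rates[%s]", g))
    resource_rates[[g]] <- rr
  }

  miss_fields <- c("symptomatic", "reversibility", "hyperreactivity")
  if (!all(miss_fields %in% names(missingness))) {
    abort("'missingness' must name %s", paste(miss_fields, collapse = ", "))
  }
  missingness <- missingness[miss_fields]
  check_prob(missingness, "missingness")

  if (length(seed) != 1L || is.na(seed) || seed != trunc(seed)) {
    abort("'seed' must be a single integer")
  }

  structure(list(n = stats::setNames(as.integer(n), groups),
                 p_symptomatic = p_symptomatic,
                 p_ics_given_symptomatic = p_ics,
                 p_reversibility_pos = p_rev,
                 p_hyperreactivity_pos = p_hyper,
                 resource_rates = resource_rates,
                 missingness = missingness,
                 seed = as.integer(seed)),
            class = "generator_params")
}

#' Placeholder resource-use Poisson means
#'
#' Direct-medical items for every child plus intervention items that are
#' only ever non-zero in the prevention groups. Placeholder values; the
#' trial's resource-use distributions are not published.
#'
#' @return Named list of per-group named rate vectors.
#' @export
default_resource_rates <- function() {
  direct <- c(gp_visit = 1.2, specialist_visit = 0.3, hospital_admission = 0.03,
              chest_xray = 0.15, ria_allergen_test = 0.40, medication = 0.8)
  interv <- c(nurse_visit = 4, hdm_impermeable_cover = 3,
              hypoallergenic_formula = 1, brochure = 1)
  none <- stats::setNames(rep(0, length(interv)), names(interv))
  list(multifaceted = c(direct, interv),
       unifaceted = c(direct, interv * 0.5),
       pfh_control = c(direct, none),
       nfh = c(direct, none))
}

# deterministic per-group substream seed; kept below 2^31 - 1
substream_seed <- function(seed, group) {
  idx <- match(group, strategy_groups())
  as.integer((abs(as.numeric(seed)) * 48271 + idx) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Draws one record per configured child: true symptomatic status, ICS
#' treatment (symptomatic children only), test outcomes conditional on
#' symptomatic status, independent Poisson resource-use counts, and
#' per-field missingness masks on the three diagnostic measurements.
#' The same seed reproduces the identical cohort.
#'
#' @param params a [generator_params()].
#' @return A cohort data frame (one row per child; see [read_cohort()]
#'   for the column schema).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  groups <- strategy_groups()
  items <- sort(unique(unlist(lapply(params$resource_rates, names))))

  gen_group <- function(g) {
    n <- params$n[[g]]
    if (n == 0L) return(NULL)
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(substream_seed(params$seed, g))

    s <- stats::rbinom(n, 1, params$p_symptomatic[[g]]) == 1
    ics <- s & stats::rbinom(n, 1, params$p_ics_given_symptomatic[[g]]) == 1
    p_rev <- ifelse(s, params$p_reversibility_pos[[g]][["symptomatic"]],
                    params$p_reversibility_pos[[g]][["asymptomatic"]])
    p_hyp <- ifelse(s, params$p_hyperreactivity_pos[[g]][["symptomatic"]],
                    params$p_hyperreactivity_pos[[g]][["asymptomatic"]])
    rev <- stats::rbinom(n, 1, p_rev) == 1
    hyp <- stats::rbinom(n, 1, p_hyp) == 1
    m <- params$missingness
    s_obs <- ifelse(stats::rbinom(n, 1, m[["symptomatic"]]) == 1, NA, s)
    rev_obs <- ifelse(stats::rbinom(n, 1, m[["reversibility"]]) == 1, NA, rev)
    hyp_obs <- ifelse(stats::rbinom(n, 1, m[["hyperreactivity"]]) == 1, NA, hyp)

    df <- data.frame(
      id = sprintf("%s_%04d", g, seq_len(n)),
      family_history = if (g == "nfh") "NFH" else "PFH",
      trial_arm = switch(g, nfh = "natural_history",
                         pfh_control = "control", "intervention"),
      airborne_compliant = switch(g, multifaceted = TRUE, unifaceted = TRUE,
                                  pfh_control = FALSE, nfh = NA),
      food_compliant = switch(g, multifaceted = TRUE, unifaceted = FALSE,
                              pfh_control = FALSE, nfh = NA),
      ics_use = ics,
      symptomatic = as.logical(s_obs),
      reversibility = as.logical(rev_obs),
      hyperreactivity = as.logical(hyp_obs),
      stringsAsFactors = FALSE
    )
    rates <- params$resource_rates[[g]]
    for (item in items) {
      rate <- if (item %in% names(rates)) rates[[item]] else 0
      df[[paste0("ru_", item)]] <- stats::rpois(n, rate)
    }
    df
  }

  out <- do.call(rbind, Filter(Negate(is.null), lapply(groups, gen_group)))
  if (is.null(out)) out <- empty_cohort(items)
  rownames(out) <- NULL
  out
}

empty_cohort <- function(items = character(0)) {
  df <- data.frame(id = character(0), family_history = character(0),
                   trial_arm = character(0), airborne_compliant = logical(0),
                   food_compliant = logical(0), ics_use = logical(0),
                   symptomatic = logical(0), reversibility = logical(0),
                   hyperreactivity = logical(0), stringsAsFactors = FALSE)
  for (item in items) df[[paste0("ru_", item)]] <- integer(0)
  df
}

# Closed-form oracle -------------------------------------------------------

#' Exact strategy expectation implied by generator parameters
#'
#' Sums over the finite outcome space (symptomatic status, treatment,
#' true test results, per-field missingness masks) — no sampling. The
#' probability of asthma avoidance is conditional on the record being
#' evaluable, mirroring the pipeline's evaluability filter; expected cost
#' is the rate-weighted sum of indexed unit prices (resource use is
#' independent of the diagnostic path).
#'
#' @param params a [generator_params()].
#' @param group one of the four strategy-group labels.
#' @param price_table a [unit_price_table()].
#' @param config a [diagnosis_config()].
#' @return A [strategy_expectation()] with `n = NA` (analytic).
#' @export
analytic_strategy_expectation <- function(params, group,
                                          price_table = default_price_table(),
                                          config = diagnosis_config()) {
  stopifnot(inherits(params, "generator_params"))
  if (!group %in% strategy_groups()) abort("unknown group '%s'", group)

  probs <- analytic_outcome_probabilities(params, group)

  # P(negative diagnosis | evaluable)
  p_eval <- 0
  p_eval_neg <- 0
  for (i in seq_len(nrow(probs$space))) {
    w <- probs$space$w[i]
    if (w == 0) next
    prof <- diagnostic_profile(
      ics_use = probs$space$ics[i],
      symptomatic = probs$space$s_obs[i],
      reversibility = probs$space$rev_obs[i],
      hyperreactivity = probs$space$hyp_obs[i])
    if (is_evaluable(prof)) {
      p_eval <- p_eval + w
      if (classify_asthma(prof, config) == "negative") {
        p_eval_neg <- p_eval_neg + w
      }
    }
  }
  if (p_eval == 0) {
    abort("no evaluable outcome has positive probability for group '%s'", group)
  }

  include_intervention <- group %in% c("multifaceted", "unifaceted")
  rates <- params$resource_rates[[group]]
  cost <- 0
  if (length(rates)) {
    prices <- indexed_prices(price_table)
    cats <- stats::setNames(price_table$items$category, price_table$items$item)
    unknown <- setdiff(names(rates), names(prices))
    if (length(unknown)) {
      abort("unknown cost item(s): %s", paste(unknown, collapse = ", "))
    }
    keep <- include_intervention | cats[names(rates)] == "direct_medical"
    cost <- sum(rates[keep] * prices[names(rates)[keep]])
  }

  strategy_expectation(group, cost, p_eval_neg / p_eval, n = NA_integer_)
}

# Joint probabilities over (true status, treatment, observed fields).
# Observed fields take values TRUE/FALSE/NA; weight w is the joint mass.
analytic_outcome_probabilities <- function(params, group) {
  ps <- params$p_symptomatic[[group]]
  pi <- params$p_ics_given_symptomatic[[group]]
  pr <- params$p_reversibility_pos[[group]]
  ph <- params$p_hyperreactivity_pos[[group]]
  m <- params$missingness

  obs_states <- function(truth, miss) {
    # (observed value, probability) pairs given the underlying truth
    list(list(val = truth, w = 1 - miss), list(val = NA, w = miss))
  }
  rows <- list()
  for (s in c(TRUE, FALSE)) {
    w_s <- if (s) ps else 1 - ps
    p_ics <- if (s) pi else 0
    for (ics in c(TRUE, FALSE)) {
      w_i <- if (ics) p_ics else 1 - p_ics
      if (w_i == 0) next
      cond <- if (s) "symptomatic" else "asymptomatic"
      for (rv in c(TRUE, FALSE)) {
        w_r <- if (rv) pr[[cond]] else 1 - pr[[cond]]
        for (hy in c(TRUE, FALSE)) {
          w_h <- if (hy) ph[[cond]] else 1 - ph[[cond]]
          for (so in obs_states(s, m[["symptomatic"]])) {
            for (ro in obs_states(rv, m[["reversibility"]])) {
              for (ho in obs_states(hy, m[["hyperreactivity"]])) {
                rows[[length(rows) + 1L]] <- data.frame(
                  s = s, ics = ics, rev = rv, hyp = hy,
                  s_obs = so$val, rev_obs = ro$val, hyp_obs = ho$val,
                  w = w_s * w_i * w_r * w_h * so$w * ro$w * ho$w)
              }
            }
          }
        }
      }
    }
  }
  list(space = do.call(rbind, rows))
}

#' Exact strategy tree implied by generator parameters
#'
#' Builds the canonical chance tree using the generator's exact branch
#' probabilities (conditional on evaluability) and the exact expected
#' cost at every terminal. Folding it back reproduces
#' [analytic_strategy_expectation()]; used to cross-check the empirical
#' tree builder.
#'
#' @inheritParams analytic_strategy_expectation
#' @return A `tree_node`.
#' @export
analytic_strategy_tree <- function(params, group,
                                   price_table = default_price_table(),
                                   config = diagnosis_config()) {
  stopifnot(inherits(params, "generator_params"))
  if (!group %in% strategy_groups()) abort("unknown group '%s'", group)
  space <- analytic_outcome_probabilities(params, group)$space

  # evaluability, path and diagnosis per outcome cell
  keep <- logical(nrow(space))
  diag <- character(nrow(space))
  for (i in seq_len(nrow(space))) {
    prof <- diagnostic_profile(space$ics[i], space$s_obs[i],
                               space$rev_obs[i], space$hyp_obs[i])
    keep[i] <- is_evaluable(prof) && space$w[i] > 0
    if (keep[i]) diag[i] <- classify_asthma(prof, config)
  }
  space <- space[keep, , drop = FALSE]
  diag <- diag[keep]
  w <- space$w / sum(space$w)
  # effective path fields as the tree builder sees them
  treated <- space$ics
  symp <- treated | (!is.na(space$s_obs) & space$s_obs)

  include_intervention <- group %in% c("multifaceted", "unifaceted")
  rates <- params$resource_rates[[group]]
  cost <- 0
  if (length(rates)) {
    prices <- indexed_prices(price_table)
    cats <- stats::setNames(price_table$items$category, price_table$items$item)
    k <- include_intervention | cats[names(rates)] == "direct_medical"
    cost <- sum(rates[k] * prices[names(rates)[k]])
  }

  diag_node <- function(sel, label) {
    p_pos <- sum(w[sel & diag == "positive"]) / sum(w[sel])
    branches <- list(
      list(label = "asthma_positive", prob = p_pos,
           node = terminal_node(cost, TRUE, paste0(label, "/positive"))),
      list(label = "asthma_negative", prob = 1 - p_pos,
           node = terminal_node(cost, FALSE, paste0(label, "/negative"))))
    branches <- Filter(function(b) b$prob > 0, branches)
    if (length(branches) == 1L) branches[[1]]$prob <- 1
    chance_node(label, branches)
  }

  p_symp <- sum(w[symp])
  branches <- list()
  if (p_symp > 0) {
    p_rx <- sum(w[symp & treated]) / p_symp
    rx_branches <- list(
      list(label = "ics", prob = p_rx,
           node = if (p_rx > 0) diag_node(symp & treated, paste0(group, "/ics/diagnosis"))),
      list(label = "no_pharmacotherapy", prob = 1 - p_rx,
           node = if (p_rx < 1) diag_node(symp & !treated, paste0(group, "/none/diagnosis"))))
    rx_branches <- Filter(function(b) b$prob > 0, rx_branches)
    if (length(rx_branches) == 1L) rx_branches[[1]]$prob <- 1
    branches[[length(branches) + 1L]] <- list(
      label = "symptomatic", prob = p_symp,
      node = chance_node(paste0(group, "/pharmacotherapy"), rx_branches))
  }
  if (p_symp < 1) {
    branches[[length(branches) + 1L]] <- list(
      label = "asymptomatic", prob = 1 - p_symp,
      node = diag_node(!symp, paste0(group, "/asymptomatic/diagnosis")))
  }
  if (length(branches) == 1L) branches[[1]]$prob <- 1
  chance_node(paste0(group, "/symptomatic?"), branches)
}

#' Read generator parameters from JSON
#'
#' Schema mirrors [generator_params()] arguments; see the packaged
#' default at `system.file("extdata", "generator_default.json",
#' package = "prevcea")`.
#'
#' @param path JSON file path.
#' @return A [generator_params()].
#' @export
read_generator_params <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (field in c("n", "p_symptomatic", "p_ics_given_symptomatic",
                  "p_reversibility_pos", "p_hyperreactivity_pos",
                  "resource_rates", "missingness", "seed")) {
    if (!is.null(cfg[[field]])) {
      val <- cfg[[field]]
      if (field %in% c("n", "p_symptomatic", "p_ics_given_symptomatic",
                       "missingness") && is.list(val)) {
        val <- unlist(val)
      }
      args[[field]] <- val
    }
  }
  do.call(generator_params, args)
}

#' Default generator parameters
#'
#' @return A [generator_params()] from the packaged default config.
#' @export
default_generator_params <- function() {
  read_generator_params(system.file("extdata", "generator_default.json",
                                    package = "prevcea", mustWork = TRUE))
}
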