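# Shared fixtures, built in code.

# Minimal price table: one direct and one intervention item, plus an
# item priced in an earlier year to exercise indexation.
tiny_price_table <- function() {
  unit_price_table(
    data.frame(
      item = c("gp_visit", "medication", "nurse_visit"),
      unit_price = c(28, 30, 35),
      price_year = c(2009, 2007, 2009),
      category = c("direct_medical", "direct_medical", "intervention"),
      stringsAsFactors = FALSE),
    index_factors = c("2007" = 1.10, "2009" = 1.0))
}

# Generator parameters with one scalar applied to all groups; counts
# default to a small cohort. Degenerate values (0/1) are allowed.
tiny_params <- function(n = c(multifaceted = 20, unifaceted = 20,
                              pfh_control = 20, nfh = 20),
                        p_symptomatic = 0.3,
                        p_ics = 0.4,
                        p_rev = 0.2,
                        p_hyper = 0.25,
                        missingness = c(symptomatic = 0,
                                        reversibility = 0,
                                        hyperreactivity = 0),
                        resource_rates = c(gp_visit = 1, medication = 0.5,
                                           nurse_visit = 2),
                        seed = 42L) {
  all_groups <- function(x) {
    stats::setNames(rep(list(x), 4),
                    c("multifaceted", "unifaceted", "pfh_control", "nfh"))
  }
  generator_params(
    n = n,
    p_symptomatic = unlist(all_groups(p_symptomatic)),
    p_ics_given_symptomatic = unlist(all_groups(p_ics)),
    p_reversibility_pos = all_groups(p_rev),
    p_hyperreactivity_pos = all_groups(p_hyper),
    resource_rates = all_groups(resource_rates),
    missingness = missingness,
    seed = seed)
}

# Hand-written evaluable cohort row.
cohort_row <- function(id, group = c("multifaceted", "unifaceted",
                                     "pfh_control", "nfh"),
                       ics = FALSE, symptomatic = FALSE,
                       reversibility = FALSE, hyperreactivity = NA,
                       gp_visit = 0L, nurse_visit = 0L) {
  group <- match.arg(group)
  data.frame(
    id = id,
    family_history = if (group == "nfh") "NFH" else "PFH",
    trial_arm = switch(group, nfh = "natural_history",
                       pfh_control = "control", "intervention"),
    airborne_compliant = switch(group, multifaceted = TRUE, unifaceted = TRUE,
                                pfh_control = FALSE, nfh = NA),
    food_compliant = switch(group, multifaceted = TRUE, unifaceted = FALSE,
                            pfh_control = FALSE, nfh = NA),
    ics_use = ics, symptomatic = symptomatic,
    reversibility = reversibility, hyperreactivity = hyperreactivity,
    ru_gp_visit = gp_visit, ru_nurse_visit = nurse_visit,
    stringsAsFactors = FALSE)
}

# Random valid chance tree for the fold-back oracle tests.
random_tree <- function(depth = 0L, max_depth = 5L) {
  if (depth >= max_depth || stats::runif(1) < 0.35) {
    return(terminal_node(stats::runif(1, 0, 1000), stats::runif(1) < 0.5,
                         paste0("t", depth)))
  }
  k <- sample(2:3, 1)
  w <- stats::rgamma(k, 1) + 1e-6
  p <- w / sum(w)
  chance_node(paste0("c", depth), lapply(seq_len(k), function(i) {
    list(label = paste0("b", i), prob = p[i],
         node = random_tree(depth + 1L, max_depth))
  }))
}

# All 2 x 3 x 3 x 3 diagnostic field combinations (TRUE/FALSE/NA).
all_profiles <- function() {
  tfna <- c(TRUE, FALSE, NA)
  expand.grid(ics = c(TRUE, FALSE), symptomatic = tfna,
              reversibility = tfna, hyperreactivity = tfna)
}
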