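# Cohort generator: determinism, degenerate cases, sampling bounds, and
# the closed-form expectation oracle.

test_that("parameter validation names the offending field", {
  expect_error(tiny_params(p_symptomatic = 1.2), "p_symptomatic")
  expect_error(tiny_params(n = c(multifaceted = -1, unifaceted = 0,
                                 pfh_control = 0, nfh = 0)), "n\\[")
  expect_error(tiny_params(resource_rates = c(gp_visit = -2)),
               "resource_rates")
  expect_error(tiny_params(missingness = c(symptomatic = 2,
                                           reversibility = 0,
                                           hyperreactivity = 0)),
               "missingness")
})

test_that("all-zero counts give an empty cohort with the full schema", {
  cohort <- generate_cohort(tiny_params(n = c(multifaceted = 0, unifaceted = 0,
                                              pfh_control = 0, nfh = 0)))
  expect_identical(nrow(cohort), 0L)
  expect_true(all(c("id", "family_history", "ics_use") %in% names(cohort)))
})

test_that("degenerate probabilities are reproduced exactly", {
  params <- tiny_params(n = c(multifaceted = 0, unifaceted = 0,
                              pfh_control = 0, nfh = 50),
                        p_symptomatic = 1)
  cohort <- generate_cohort(params)
  expect_identical(nrow(cohort), 50L)
  expect_true(all(cohort$symptomatic))
})

test_that("the same seed reproduces the identical cohort; substreams are independent", {
  params <- tiny_params(seed = 123L)
  expect_identical(generate_cohort(params), generate_cohort(params))

  other_seed <- tiny_params(seed = 124L)
  expect_false(identical(generate_cohort(params), generate_cohort(other_seed)))

  # resizing one group leaves the others' substreams untouched
  bigger_nfh <- tiny_params(n = c(multifaceted = 20, unifaceted = 20,
                                  pfh_control = 20, nfh = 77), seed = 123L)
  a <- generate_cohort(params)
  b <- generate_cohort(bigger_nfh)
  expect_identical(a[a$family_history == "PFH", ],
                   b[b$family_history == "PFH", ])
})

test_that("sampled symptomatic fraction is within 3 binomial SE at n = 10,000", {
  params <- tiny_params(n = c(multifaceted = 0, unifaceted = 0,
                              pfh_control = 0, nfh = 10000),
                        p_symptomatic = 0.3, seed = 5L)
  cohort <- generate_cohort(params)
  frac <- mean(cohort$symptomatic)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("degenerate parameters collapse the oracle to the single path", {
  params <- tiny_params(p_symptomatic = 1, p_ics = 1, p_rev = 0, p_hyper = 0,
                        resource_rates = c(gp_visit = 0))
  # every child: ICS+, both tests negative -> the sensitivity cell
  neg <- analytic_strategy_expectation(params, "nfh", tiny_price_table(),
                                       diagnosis_config("negative"))
  pos <- analytic_strategy_expectation(params, "nfh", tiny_price_table(),
                                       diagnosis_config("positive"))
  expect_equal(neg$p_asthma_avoided, 1)
  expect_equal(pos$p_asthma_avoided, 0)
  expect_equal(neg$expected_cost, 0)

  # no asthma-implying outcome has positive probability -> avoidance 1
  safe <- tiny_params(p_symptomatic = 0.4, p_ics = 0, p_rev = 0, p_hyper = 0)
  expect_equal(analytic_strategy_expectation(safe, "multifaceted",
                                             tiny_price_table())$p_asthma_avoided,
               1)
  expect_error(analytic_strategy_expectation(params, "phantom"), "phantom")
})

test_that("Monte-Carlo means at n = 100,000 match the analytic oracle", {
  params <- tiny_params(n = c(multifaceted = 0, unifaceted = 0,
                              pfh_control = 0, nfh = 100000),
                        p_symptomatic = 0.3, p_ics = 0.4,
                        p_rev = 0.2, p_hyper = 0.25,
                        missingness = c(symptomatic = 0.05,
                                        reversibility = 0.1,
                                        hyperreactivity = 0.1),
                        seed = 31L)
  pt <- tiny_price_table()
  oracle <- analytic_strategy_expectation(params, "nfh", pt)

  cohort <- generate_cohort(params)
  kept <- filter_evaluable(cohort)$kept
  n <- nrow(kept)
  diag <- prevcea:::cohort_diagnose(kept)
  p_hat <- mean(diag == "negative")
  se_p <- sqrt(p_hat * (1 - p_hat) / n)
  expect_lt(abs(p_hat - oracle$p_asthma_avoided), 3 * se_p)

  costs <- prevcea:::cohort_costs(kept, pt)
  se_c <- stats::sd(costs) / sqrt(n)
  # half-cent rounding bias is negligible against the Monte-Carlo SE
  expect_lt(abs(mean(costs) - oracle$expected_cost), 3 * se_c + 0.005)
})

test_that("fold-back of the exact-probability tree equals the oracle to 1e-9", {
  pt <- tiny_price_table()
  cases <- list(
    tiny_params(),
    tiny_params(p_symptomatic = 0.05, p_ics = 0.9, p_rev = 0.5, p_hyper = 0.01,
                missingness = c(symptomatic = 0.2, reversibility = 0.15,
                                hyperreactivity = 0.3)),
    tiny_params(p_symptomatic = 0.8, p_ics = 0.1, p_rev = 0.02, p_hyper = 0.6)
  )
  for (params in cases) {
    for (group in c("multifaceted", "pfh_control")) {
      oracle <- analytic_strategy_expectation(params, group, pt)
      fb <- fold_back(analytic_strategy_tree(params, group, pt))
      expect_lt(abs(fb$expected_cost - oracle$expected_cost), 1e-9)
      expect_lt(abs(fb$p_asthma_avoided - oracle$p_asthma_avoided), 1e-9)
    }
  }
})

test_that("conditional test probabilities flow through generator and oracle", {
  params <- generator_params(
    n = c(multifaceted = 0, unifaceted = 0, pfh_control = 0, nfh = 20000),
    p_symptomatic = c(multifaceted = 0.3, unifaceted = 0.3,
                      pfh_control = 0.3, nfh = 0.3),
    p_ics_given_symptomatic = c(multifaceted = 0, unifaceted = 0,
                                pfh_control = 0, nfh = 0),
    p_reversibility_pos = list(
      multifaceted = 0.1, unifaceted = 0.1, pfh_control = 0.1,
      nfh = c(symptomatic = 0.6, asymptomatic = 0.05)),
    p_hyperreactivity_pos = list(multifaceted = 0.1, unifaceted = 0.1,
                                 pfh_control = 0.1, nfh = 0.1),
    resource_rates = c(gp_visit = 1),
    missingness = c(symptomatic = 0, reversibility = 0, hyperreactivity = 0),
    seed = 8L)
  cohort <- generate_cohort(params)
  p_rev_symp <- mean(cohort$reversibility[cohort$symptomatic])
  p_rev_asym <- mean(cohort$reversibility[!cohort$symptomatic])
  n_s <- sum(cohort$symptomatic)
  expect_lt(abs(p_rev_symp - 0.6), 3 * sqrt(0.6 * 0.4 / n_s))
  expect_lt(abs(p_rev_asym - 0.05), 3 * sqrt(0.05 * 0.95 / (20000 - n_s)))
})
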