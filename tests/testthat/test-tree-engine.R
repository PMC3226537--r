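# Branch-probability estimation, tree construction, fold-back and the
# path-enumeration oracle.

test_that("estimate_branch_probability is the count ratio with an empty-cell policy", {
  expect_equal(estimate_branch_probability(3, 1), 0.75)
  expect_equal(estimate_branch_probability(0, 10), 0)
  expect_equal(estimate_branch_probability(0, 0, policy = "additive"), 0.5)
  expect_error(estimate_branch_probability(0, 0, policy = "strict",
                                           branch = "rx-node"), "rx-node")
  expect_true(is.na(estimate_branch_probability(0, 0, policy = "collapse")))
  expect_error(estimate_branch_probability(-1, 2), "n_event")
})

test_that("fold_back handles leaves and simple chance nodes", {
  leaf <- terminal_node(10, asthma = FALSE)
  expect_equal(fold_back(leaf), list(expected_cost = 10, p_asthma_avoided = 1))
  two <- chance_node("flip", list(
    list(label = "a", prob = 0.5, node = terminal_node(0, FALSE)),
    list(label = "b", prob = 0.5, node = terminal_node(100, TRUE))))
  expect_equal(fold_back(two), list(expected_cost = 50, p_asthma_avoided = 0.5))
  expect_error(chance_node("bad", list(
    list(label = "a", prob = 0.6, node = leaf),
    list(label = "b", prob = 0.6, node = leaf))), "bad")
})

test_that("fold_back equals the path-enumeration oracle on random trees", {
  set.seed(7)
  for (i in 1:200) {
    tree <- random_tree()
    paths <- enumerate_paths(tree)
    expect_lt(abs(sum(paths$probability) - 1), 1e-9)
    fb <- fold_back(tree)
    expect_lt(abs(fb$expected_cost - sum(paths$probability * paths$cost)), 1e-9)
    expect_lt(abs(fb$p_asthma_avoided -
                    sum(paths$probability * !paths$asthma)), 1e-9)
    expect_gte(fb$p_asthma_avoided, 0)
    expect_lte(fb$p_asthma_avoided, 1)
    expect_gte(fb$expected_cost, min(paths$cost) - 1e-9)
    expect_lte(fb$expected_cost, max(paths$cost) + 1e-9)
  }
})

test_that("scaling terminal costs scales expected cost and leaves the outcome alone", {
  scale_tree <- function(node, k) {
    if (node$kind == "terminal") {
      return(terminal_node(node$payoff$cost * k, node$payoff$asthma, node$label))
    }
    chance_node(node$label, lapply(node$branches, function(b) {
      list(label = b$label, prob = b$prob, node = scale_tree(b$node, k))
    }))
  }
  set.seed(11)
  for (i in 1:20) {
    tree <- random_tree()
    fb <- fold_back(tree)
    fb3 <- fold_back(scale_tree(tree, 3))
    expect_equal(fb3$expected_cost, 3 * fb$expected_cost)
    expect_equal(fb3$p_asthma_avoided, fb$p_asthma_avoided)
  }
})

test_that("a two-path pencil-and-paper cohort builds the expected tree", {
  pt <- tiny_price_table()
  # symptomatic untreated, reversibility positive -> asthma; 28 / 56 EUR
  s1 <- cohort_row("s1", "nfh", symptomatic = TRUE, reversibility = TRUE,
                   gp_visit = 1L)
  s2 <- cohort_row("s2", "nfh", symptomatic = TRUE, reversibility = TRUE,
                   gp_visit = 2L)
  # asymptomatic, reversibility negative -> no asthma; 84 / 112 EUR
  a1 <- cohort_row("a1", "nfh", gp_visit = 3L)
  a2 <- cohort_row("a2", "nfh", gp_visit = 4L)
  tree <- build_strategy_tree(rbind(s1, s2, a1, a2), pt)

  expect_identical(tree$kind, "chance")
  probs <- vapply(tree$branches, `[[`, numeric(1), "prob")
  expect_equal(unname(probs), c(0.5, 0.5))
  fb <- fold_back(tree)
  expect_equal(fb$expected_cost, 0.5 * mean(c(28, 56)) + 0.5 * mean(c(84, 112)))
  expect_equal(fb$p_asthma_avoided, 0.5)
  # nurse visits cost nothing in a non-prevention stratum
  paths <- enumerate_paths(tree)
  expect_identical(nrow(paths), 2L)
})

test_that("a degenerate cohort yields a single unit-probability path", {
  pt <- tiny_price_table()
  cohort <- rbind(cohort_row("a", "nfh", gp_visit = 1L),
                  cohort_row("b", "nfh", gp_visit = 1L))
  tree <- build_strategy_tree(cohort, pt)
  paths <- enumerate_paths(tree)
  expect_identical(nrow(paths), 1L)
  expect_equal(paths$probability, 1)
  expect_equal(paths$cost, 28)
  expect_false(paths$asthma)
  expect_error(build_strategy_tree(cohort[0, ], pt), "no records")
})

test_that("branch probabilities recover generator values at n = 10,000", {
  params <- tiny_params(n = c(multifaceted = 10000, unifaceted = 0,
                              pfh_control = 0, nfh = 0),
                        p_symptomatic = 0.3, p_ics = 0.4,
                        p_rev = 0.2, p_hyper = 0.25, seed = 99L)
  cohort <- generate_cohort(params)
  tree <- build_strategy_tree(cohort, tiny_price_table())
  n <- nrow(cohort)

  p_symp_hat <- tree$branches[[1]]$prob
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(p_symp_hat - 0.3), 3 * se)

  rx_node <- tree$branches[[1]]$node
  expect_match(rx_node$label, "pharmacotherapy")
  p_rx_hat <- rx_node$branches[[1]]$prob
  n_symp <- round(p_symp_hat * n)
  expect_lt(abs(p_rx_hat - 0.4), 3 * sqrt(0.4 * 0.6 / n_symp))

  # diagnosis on the symptomatic untreated path: positive iff rev+ or
  # (rev- and hyper+)
  diag_node <- rx_node$branches[[2]]$node
  p_pos_exp <- 0.2 + 0.8 * 0.25
  p_pos_hat <- diag_node$branches[[1]]$prob
  n_path <- round(n_symp * (1 - p_rx_hat))
  expect_lt(abs(p_pos_hat - p_pos_exp),
            3 * sqrt(p_pos_exp * (1 - p_pos_exp) / n_path))
})

test_that("empty cells follow the configured policy", {
  pt <- tiny_price_table()
  # every child symptomatic and treated: the untreated diagnosis cell
  # never occurs, and under additive smoothing the root gains no mass
  # because zero-probability branches are pruned exactly
  cohort <- rbind(
    cohort_row("a", "nfh", ics = TRUE, reversibility = TRUE,
               hyperreactivity = TRUE, gp_visit = 1L),
    cohort_row("b", "nfh", ics = TRUE, reversibility = FALSE,
               hyperreactivity = FALSE, gp_visit = 1L))
  tree <- build_strategy_tree(cohort, pt, policy = "additive")
  paths <- enumerate_paths(tree)
  expect_equal(sum(paths$probability), 1)
  expect_identical(attr(tree, "empty_cells"), character(0))
  # strict errors only when an empty cell is actually reached
  expect_silent(build_strategy_tree(cohort, pt, policy = "strict"))
})

test_that("trees survive a JSON round trip", {
  set.seed(3)
  tree <- random_tree()
  rebuilt <- tree_from_json(tree_to_json(tree))
  expect_equal(fold_back(rebuilt), fold_back(tree))
  expect_equal(enumerate_paths(rebuilt), enumerate_paths(tree))
})
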