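# Tree validation, expected-value rollback and outcome probabilities.

test_that("validation passes the published arms and flags broken trees", {
  expect_length(validate_tree(noint_strategy()), 0)
  expect_length(validate_tree(supp_strategy()), 0)

  # the raw published pair 17.2% / 87.2% does not normalize
  bad <- strategy("raw", chance_node(list(
    list(p = 0.172, node = terminal_node(0, 0.76)),
    list(p = 0.872, node = terminal_node(335.4, 0.545)))))
  v <- validate_tree(bad)
  expect_length(v, 1)
  expect_match(v, "sum to 1.044")

  single <- strategy("deg", chance_node(list(
    list(p = 1, node = terminal_node(0, 0.5)))))
  expect_match(validate_tree(single), "at least 2", all = FALSE)

  neg <- strategy("neg", chance_node(list(
    list(p = 0.5, node = terminal_node(-5, 0.5)),
    list(p = 0.5, node = terminal_node(0, 1.5)))))
  v <- validate_tree(neg)
  expect_match(v, "negative", all = FALSE)
  expect_match(v, "outside \\[0, 1\\]", all = FALSE)
})

test_that("rollback reproduces the published base case by hand arithmetic", {
  # P(depression | no intervention) = 0.76*0.314 + 0.24*0.16 = 0.27704
  noint <- rollback(noint_strategy())
  expect_equal(noint$expected_cost, 0.27704 * 335.4, tolerance = 1e-12)
  expect_equal(noint$expected_cost, 92.92, tolerance = 0.001)
  expect_equal(noint$expected_effect,
               0.27704 * 0.545 + 0.72296 * 0.76, tolerance = 1e-12)
  expect_equal(noint$expected_effect, 0.7004, tolerance = 1e-4)

  # P(depression | supplementation) = 0.172*0.314 + 0.828*0.16
  supp <- rollback(supp_strategy())
  expect_equal(supp$expected_cost, 0.604 + 0.186488 * 335.4,
               tolerance = 1e-12)
  expect_equal(supp$expected_cost, 63.15, tolerance = 0.005)
  expect_equal(supp$expected_effect, 0.7199, tolerance = 1e-4)
})

test_that("a bare terminal root yields upfront cost plus payoffs", {
  s <- strategy("flat", terminal_node(10, 0.9), upfront_cost = 2.5)
  r <- rollback(s)
  expect_equal(r$expected_cost, 12.5)
  expect_equal(r$expected_effect, 0.9)
})

test_that("rollback equals brute-force path enumeration on random trees", {
  set.seed(2024)
  for (i in 1:40) {
    strat <- random_strategy(max_depth = 4)
    oracle <- brute_force_ev(strat)
    expect_equal(oracle$total_prob, 1, tolerance = 1e-9)  # conservation
    got <- rollback(strat)
    expect_equal(got$expected_cost, oracle$cost, tolerance = 1e-9)
    expect_equal(got$expected_effect, oracle$effect, tolerance = 1e-9)
  }
})

test_that("outcome probability equals enumerated path mass into labelled leaves", {
  expect_equal(outcome_probability(noint_strategy()), 0.27704,
               tolerance = 1e-12)
  expect_equal(outcome_probability(supp_strategy()), 0.186488,
               tolerance = 1e-12)

  set.seed(77)
  for (i in 1:20) {
    strat <- random_strategy(max_depth = 3)
    paths <- enumerate_paths(strat)
    want <- sum(paths$prob[!is.na(paths$outcome) &
                             paths$outcome == "depression"])
    expect_equal(outcome_probability(strat), want, tolerance = 1e-9)
  }

  healthy_only <- strategy("none", chance_node(list(
    list(p = 0.3, node = terminal_node(0, 0.8, outcome = "healthy")),
    list(p = 0.7, node = terminal_node(0, 0.9, outcome = "healthy")))))
  expect_equal(outcome_probability(healthy_only), 0)

  unlabelled <- strategy("none", chance_node(list(
    list(p = 0.5, node = terminal_node(0, 0.8)),
    list(p = 0.5, node = terminal_node(0, 0.9)))))
  expect_error(outcome_probability(unlabelled), "no outcome-labelled")
})

test_that("expected values respond monotonically to payoffs and risk", {
  base <- rollback(noint_strategy())

  # raising a leaf utility raises expected effect
  up <- noint_strategy()
  up$root$branches[[1]]$node$branches[[1]]$node$utility <- 0.60
  expect_gt(rollback(up)$expected_effect, base$expected_effect)

  # shifting probability into the depressed branch (which carries the
  # higher cost and lower utility) raises cost, lowers effect
  risky <- noint_strategy()
  risky$root$branches[[1]]$node <- depression_subtree(0.40)
  r <- rollback(risky)
  expect_gt(r$expected_cost, base$expected_cost)
  expect_lt(r$expected_effect, base$expected_effect)
})

test_that("parameter references resolve from the environment they are given", {
  s <- strategy("ref", chance_node(list(
    list(p = "p_bad", node = terminal_node("c_bad", "u_bad",
                                           outcome = "depression")),
    list(p = 0.7, node = terminal_node(0, 0.8)))))
  params <- c(p_bad = 0.3, c_bad = 100, u_bad = 0.5)
  r <- rollback(s, params)
  expect_equal(r$expected_cost, 30)
  expect_equal(r$expected_effect, 0.3 * 0.5 + 0.7 * 0.8)
  expect_error(rollback(s, params[-2]), "unresolvable|unresolved")
})
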