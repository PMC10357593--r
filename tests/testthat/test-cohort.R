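# Synthetic student cohorts: the microsimulation oracle for the tree.

test_that("cohort means converge to the rollback expectations (both arms)", {
  model <- vitd_model()
  fit <- cea(model)
  targets <- list(
    no_intervention = fit$results[["No Intervention"]],
    supplementation = fit$results[["Vitamin D Supplementation"]])
  risks <- c(no_intervention = 0.27704, supplementation = 0.186488)
  for (arm in names(targets)) {
    students <- generate_cohort(model, n = 1e5, arm = arm, seed = 31)
    s <- summarize_cohort(students)
    expect_lt(abs(s$mean_cost - targets[[arm]]$expected_cost),
              3 * s$se_cost)
    expect_lt(abs(s$mean_utility - targets[[arm]]$expected_effect),
              3 * s$se_utility)
    se_bin <- sqrt(risks[[arm]] * (1 - risks[[arm]]) / 1e5)
    expect_lt(abs(s$depression_rate - risks[[arm]]), 3 * se_bin)
  }
})

test_that("records are internally consistent and reproducible", {
  model <- vitd_model()
  x <- generate_cohort(model, n = 5000, arm = "supplementation",
                       adherence = 0.785, seed = 1)
  expect_identical(x, generate_cohort(model, n = 5000,
                                      arm = "supplementation",
                                      adherence = 0.785, seed = 1))
  # payoff bookkeeping follows the flags exactly
  expect_equal(x$cost,
               ifelse(x$depressed, 335.4, 0) +
                 ifelse(x$received_supplement, 0.604, 0))
  expect_equal(x$utility, ifelse(x$depressed, 0.545, 0.76))
  # nobody in the control arm receives supplements
  y <- generate_cohort(model, n = 100, arm = "no_intervention", seed = 2)
  expect_false(any(y$received_supplement))
  # single-student cohort is a valid record
  one <- generate_cohort(model, n = 1, arm = "supplementation", seed = 3)
  expect_equal(nrow(one), 1)
  expect_true(one$cost >= 0 && one$utility >= 0 && one$utility <= 1)
})

test_that("empirical conditional depression laws match the branch inputs", {
  model <- vitd_model()
  x <- generate_cohort(model, n = 1e5, arm = "no_intervention", seed = 17)
  for (cond in list(list(sel = x$deficient, p = 0.314),
                    list(sel = !x$deficient, p = 0.16))) {
    n <- sum(cond$sel)
    rate <- mean(x$depressed[cond$sel])
    expect_lt(abs(rate - cond$p), 3 * sqrt(cond$p * (1 - cond$p) / n))
  }
})

test_that("zero adherence reproduces the control arm's distribution", {
  model <- vitd_model()
  a0 <- generate_cohort(model, n = 50000, arm = "supplementation",
                        adherence = 0, seed = 23)
  ctrl <- generate_cohort(model, n = 50000, arm = "no_intervention",
                          seed = 23)
  expect_false(any(a0$received_supplement))
  # same seed, same Bernoulli stream apart from the uptake draws
  expect_equal(mean(a0$deficient), mean(ctrl$deficient),
               tolerance = 0.01)
  expect_equal(mean(a0$depressed), mean(ctrl$depressed),
               tolerance = 0.015)
})

test_that("depression rate decreases as adherence increases", {
  model <- vitd_model()
  rates <- vapply(c(0, 0.785, 1), function(a)
    mean(generate_cohort(model, n = 2e5, arm = "supplementation",
                         adherence = a, seed = 41)$depressed),
    numeric(1))
  expect_true(rates[3] <= rates[2])
  expect_true(rates[2] <= rates[1])
})

test_that("summaries validate input and do plain arithmetic", {
  hand <- data.frame(
    id = 1:2, arm = "no_intervention",
    received_supplement = FALSE, deficient = c(TRUE, FALSE),
    depressed = c(TRUE, TRUE), cost = c(335.4, 335.4),
    utility = c(0.545, 0.545))
  s <- summarize_cohort(hand)
  expect_equal(s$depression_rate, 1)
  expect_equal(s$mean_utility, 0.545)

  two <- hand
  two$depressed <- c(TRUE, FALSE)
  two$cost <- c(335.4, 0)
  expect_equal(summarize_cohort(two)$mean_cost, 167.7)

  mixed <- hand
  mixed$arm <- c("no_intervention", "supplementation")
  expect_error(summarize_cohort(mixed), "mixed arms")
  expect_error(summarize_cohort(hand[0, ]), "non-empty")
  expect_error(generate_cohort(vitd_model(), n = 0,
                               arm = "supplementation"), "positive count")
})

test_that("cohort tables round-trip through CSV with documented encoding", {
  model <- vitd_model()
  x <- generate_cohort(model, n = 200, arm = "supplementation",
                       adherence = 0.785, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(x, path)
  header <- readLines(path, n = 1)
  expect_identical(header, paste0('"id","arm","received_supplement",',
                                  '"deficient","depressed","cost","utility"'))
  y <- read_cohort(path)
  expect_equal(y, x)
})

test_that("the simulate method draws a cohort from the model", {
  model <- vitd_model()
  x <- simulate(model, nsim = 500, seed = 9, arm = "no_intervention")
  expect_equal(nrow(x), 500)
  expect_identical(x, generate_cohort(model, 500, "no_intervention",
                                      seed = 9))
})
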