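test_that("exponential factor probability matches hand-checked values", {
  expect_equal(round(p_naf_exponential(0.006, 1), 6), 0.005982)
  expect_equal(round(p_naf_exponential(0.006, 10), 6), 0.058235)
  expect_equal(p_naf_exponential(0, 25), 0)
  expect_error(p_naf_exponential(-0.01, 1), ">= 0")
  expect_error(p_naf_exponential(0.01, -1), ">= 0")
})

test_that("independent OR/AND combination rules behave as gates", {
  p <- p_naf_exponential(c(0.006, 0.004, 0.010), 10)
  expect_equal(round(p_or(p), 5), 0.18127)
  expect_equal(p_or(0.37), 0.37)          # single input: identity
  expect_equal(p_or(c(0.2, 1, 0.5)), 1)   # certainty absorbs
  expect_equal(p_and(c(0.5, 0.5)), 0.25)
  expect_equal(p_and(c(0.9, 0, 0.7)), 0)  # impossibility absorbs
  expect_error(p_or(c(0.2, 1.3)), "\\[0, 1\\]")
  expect_error(p_and(numeric(0)), "at least one")
})

test_that("OR and AND are symmetric in their arguments; PAND is not", {
  p <- c(0.1, 0.35, 0.6)
  expect_equal(p_or(p), p_or(rev(p)))
  expect_equal(p_and(p), p_and(rev(p)))
  expect_false(isTRUE(all.equal(p_pand_exponential(c(0.01, 0.05), 10),
                                p_pand_exponential(c(0.05, 0.01), 10))))
})

test_that("single-event PAND collapses to the exponential CDF", {
  expect_equal(round(p_pand_exponential(0.006, 10), 6), 0.058235)
  expect_equal(p_pand_exponential(0.03, 0), 0)
})

test_that("ordered-occurrence probability matches a sampling oracle", {
  set.seed(91)
  for (rates in list(c(0.01, 0.02), c(0.08, 0.03), c(0.05, 0.07, 0.02))) {
    oracle <- mc_pand_oracle(rates, t = 10, n_draws = 2e5)
    p <- p_pand_exponential(rates, 10)
    expect_lt(abs(p - oracle$p), 3 * oracle$se)
  }
})

test_that("ordering restricts the joint event: PAND <= AND of marginals", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:4, 1)
    rates <- stats::runif(n, 0.005, 0.3)
    t <- stats::runif(1, 1, 30)
    expect_lte(p_pand_exponential(rates, t),
               p_and(p_naf_exponential(rates, t)) + 1e-12)
    expect_gte(p_pand_exponential(rates, t), 0)
  }
})

test_that("orderings of a PAND partition its AND event", {
  # the six orderings of three distinct events are disjoint and exhaust the
  # event that all three occurred
  rates <- c(0.04, 0.09, 0.015)
  t <- 12
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  total <- sum(vapply(perms, function(pm)
    p_pand_exponential(rates[pm], t), 0))
  expect_equal(total, p_and(p_naf_exponential(rates, t)), tolerance = 1e-9)
})

test_that("analytic top probability reproduces the worked scenario", {
  sc <- scenario_tree()
  expect_equal(round(analytic_top_probability(sc, 10), 5), 0.18127)
  expect_equal(analytic_top_probability(sc, 0), 0)
})

test_that("constant-rate flattening: OR tree equals 1 - exp(-sum r * d)", {
  # all-constant version of the case-study tree: every pathway is an OR of
  # exponential leaves apart from the AND pair, whose product term is
  # negligible at these magnitudes
  rates <- c(SocSup = 2.529e-4, HeaAcc = 1.2e-4, NoMed = 3.448e-4,
             Forgot = 4.897e-3, Other = 5.002e-3, NoSym = 5.931e-3,
             ClinImp = 1.379e-4, NoTab = 3.448e-4, PriKno = 9.6e-5,
             SidEff = 8.315e-3)
  tr <- flat_tree(rates)
  expect_equal(analytic_top_probability(tr, 10),
               1 - exp(-sum(rates) * 10), tolerance = 1e-12)
})

test_that("non-constant leaves are rejected with a pointer to the simulator", {
  expect_error(analytic_top_probability(covid_tree(), 10),
               "simulate_cohort")
})

test_that("top probability is monotone in duration and in every leaf rate", {
  set.seed(23)
  tr <- random_constant_tree(5)
  probs <- vapply(seq(0, 40, by = 2),
                  function(d) analytic_top_probability(tr, d), 0)
  expect_true(all(diff(probs) >= -1e-12))
  expect_true(all(probs >= 0 & probs <= 1))
  base <- analytic_top_probability(tr, 10)
  for (id in basic_ids(tr)) {
    bumped <- tr
    bumped$nodes[[id]]$rate$rate <- bumped$nodes[[id]]$rate$rate * 1.5
    expect_gte(analytic_top_probability(bumped, 10), base - 1e-12)
  }
})
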