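test_that("null hazards produce a fully adherent cohort", {
  tr <- flat_tree(c(A = 0, B = 0))
  sim <- simulate_cohort(tr, sim_config(patients = 200, days = 5, seed = 3))
  expect_equal(sim$final_mean, 0)
  expect_equal(sim$nac_by_day, rep(0L, 5))
  expect_error(contributions(sim), "undefined")
})

test_that("a single constant leaf reproduces its exponential closed form", {
  tr <- flat_tree(c(FORG = 0.006))
  sim <- simulate_cohort(tr, sim_config(patients = 4000, days = 10, seed = 9))
  p <- 0.058235
  se <- sqrt(p * (1 - p) / 4000)
  expect_lt(abs(sim$final_mean - p), 3 * se)
  expect_equal(contributions(sim)$factor[["FORG"]], 100)
})

test_that("runs are bit-identical under the same seed and config", {
  cv <- covid_tree()
  a <- simulate_cohort(cv, sim_config(patients = 300, seed = 5))
  b <- simulate_cohort(cv, sim_config(patients = 300, seed = 5))
  expect_identical(a, b)
  c_ <- simulate_cohort(cv, sim_config(patients = 300, seed = 6))
  expect_false(identical(a$attributed, c_$attributed))
})

test_that("counts are conserved and trajectories monotone", {
  cv <- covid_tree()
  sim <- simulate_cohort(cv, sim_config(patients = 500, seed = 12))
  expect_equal(sim$adherent + sim$non_adherent, 500)
  expect_true(all(diff(sim$nac_by_day) >= 0))
  expect_true(all(sim$p_na_by_day >= 0 & sim$p_na_by_day <= 1))
  expect_equal(sim$nac_by_day[sim$days], sim$non_adherent)
  # attribution iff non-adherent, with discontinuation day recorded
  expect_identical(is.na(sim$attributed), is.na(sim$discontinuation_day))
  expect_equal(sum(!is.na(sim$attributed)), sim$non_adherent)
  co <- contributions(sim)
  expect_equal(sum(co$factor), 100, tolerance = 1e-9)
  expect_equal(sum(co$dimension), 100, tolerance = 1e-9)
})

test_that("competing equal-rate risks split attribution evenly", {
  tr <- flat_tree(c(A = 0.02, B = 0.02))
  sim <- simulate_cohort(tr, sim_config(patients = 3000, days = 10,
                                        seed = 21))
  co <- contributions(sim)
  se_share <- 100 * sqrt(0.25 / co$n_events)
  expect_lt(abs(co$factor[["A"]] - 50), 3 * se_share)
})

test_that("simulation agrees with the analytic engine on random trees", {
  set.seed(31)
  for (rep in 1:4) {
    tr <- random_constant_tree(sample(2:6, 1))
    p <- analytic_top_probability(tr, 10)
    sim <- simulate_cohort(tr, sim_config(patients = 1000, days = 10,
                                          seed = 100 + rep))
    se <- sqrt(p * (1 - p) / 1000)
    expect_lt(abs(sim$final_mean - p), 3 * se + 1e-6)
  }
})

test_that("halving the timestep leaves the final mean within noise", {
  cv <- covid_tree()
  h1 <- simulate_cohort(cv, sim_config(patients = 1000, timestep = 1,
                                       seed = 41, replicates = 8))
  h2 <- simulate_cohort(cv, sim_config(patients = 1000, timestep = 2,
                                       seed = 61, replicates = 8))
  se <- sqrt(0.22 * 0.78 / (1000 * 8))
  expect_lt(abs(h1$final_mean - h2$final_mean), 3 * sqrt(2) * se)
})

test_that("age-stratified and decaying leaves drive the hazard as specified", {
  # decaying leaf: cumulative hazard is sum over days of the floored rate
  tr <- nat_tree(list(
    nat_node("T", "top", gate = "OR", children = "P"),
    nat_node("P", "basic", rate = rate_linear_decay(0.08, 0.2))))
  sim <- simulate_cohort(tr, sim_config(patients = 4000, days = 10,
                                        seed = 77))
  expected <- 1 - exp(-sum(pmax(0, 0.08 * (1 - 0.2 * (0:9)))))
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_lt(abs(sim$final_mean - expected), 3 * se)

  # stratified leaf: population mix realises the weighted-average hazard
  bands <- data.frame(label = c("y", "m", "o"),
                      rate = c(0.09, 0.02, 0.05), weight = c(0.5, 0.3, 0.2))
  tr2 <- nat_tree(list(
    nat_node("T", "top", gate = "OR", children = "S"),
    nat_node("S", "basic", rate = rate_age_stratified(bands))))
  sim2 <- simulate_cohort(tr2, sim_config(patients = 4000, days = 10,
                                          seed = 78))
  expected2 <- sum(bands$weight * (1 - exp(-bands$rate * 10)))
  se2 <- sqrt(expected2 * (1 - expected2) / 4000)
  expect_lt(abs(sim2$final_mean - expected2), 3 * se2)
})

test_that("repairable subsystems fire only when down at the dosing step", {
  # never-failing subsystem: no discontinuations through the supply path
  tr <- nat_tree(list(
    nat_node("T", "top", gate = "OR", children = "R"),
    nat_node("R", "basic", rate = rate_repairable(0, 4))))
  sim <- simulate_cohort(tr, sim_config(patients = 200, days = 5, seed = 2))
  expect_equal(sim$non_adherent, 0)

  # an AND pair fires for nobody when one member never fails
  pair <- nat_tree(list(
    nat_node("T", "top", gate = "AND", children = c("R1", "R2")),
    nat_node("R1", "basic", rate = rate_repairable(5, 6)),
    nat_node("R2", "basic", rate = rate_repairable(0, 6))))
  simp <- simulate_cohort(pair, sim_config(patients = 200, days = 5,
                                           seed = 2))
  expect_equal(simp$non_adherent, 0)

  # a frequently failing single subsystem matches its renewal unavailability
  often <- nat_tree(list(
    nat_node("T", "top", gate = "OR", children = "R"),
    nat_node("R", "basic", rate = rate_repairable(2, 2))))
  ens <- simulate_cohort(often, sim_config(patients = 500, days = 10,
                                           seed = 19, replicates = 20))
  u <- (2 / 24) / (1 / 2 + 2 / 24)      # MTTR / (MTTF + MTTR)
  expected <- 1 - (1 - u)^10            # one dosing check per day
  expect_lt(abs(ens$final_mean - expected), 0.08)
})

test_that("interventions scale hazards and never worsen the cohort", {
  cv <- covid_tree()
  cfg <- sim_config(patients = 800, seed = 33)
  noop <- apply_improvement(cv, c(SidEff = 0))
  expect_identical(simulate_cohort(cv, cfg), simulate_cohort(noop, cfg))

  cut <- apply_improvement(cv, c(SidEff = 0.5))
  expect_equal(cut$nodes$SidEff$rate$rate, cv$nodes$SidEff$rate$rate * 0.5)
  expect_equal(cv$nodes$SidEff$rate$rate, 8.315e-3)  # original untouched
  # common random numbers: the improved fired-event set is a subset of the
  # baseline one, so any reduction is monotone run by run
  for (seed in 1:3) {
    b <- simulate_cohort(cv, sim_config(patients = 800, seed = seed))
    i <- simulate_cohort(cut, sim_config(patients = 800, seed = seed))
    expect_lte(i$non_adherent, b$non_adherent)
  }
  expect_error(apply_improvement(cv, c(Nope = 0.2)), "unknown factor")
  expect_error(apply_improvement(cv, c(PatRel = 0.2)), "not a basic factor")
  expect_error(apply_improvement(cv, c(SidEff = 1.5)), "\\[0, 1\\]")
})

test_that("uncertainty summary applies the Bernoulli closed forms", {
  fake <- structure(list(patients = 1000, final_mean = 0.22),
                    class = "nata_sim")
  s <- summarize_uncertainty(fake)
  expect_equal(s$sd, sqrt(0.22 * 0.78))
  expect_equal(round(s$sd, 2), 0.41)
  expect_equal(s$ci5, 0.22 - 1.645 * sqrt(0.22 * 0.78 / 1000))
  expect_equal(round(s$ci5, 2), 0.20)
  expect_equal(round(s$ci95, 2), 0.24)
  fake$final_mean <- 0.187
  expect_equal(round(summarize_uncertainty(fake)$sd, 2), 0.39)
  fake$final_mean <- 0
  s0 <- summarize_uncertainty(fake)
  expect_equal(c(s0$sd, s0$ci5, s0$ci95), c(0, 0, 0))
})

test_that("replicated runs pool means and attributions", {
  tr <- flat_tree(c(A = 0.02, B = 0.01))
  ens <- simulate_cohort(tr, sim_config(patients = 400, seed = 8,
                                        replicates = 3))
  expect_s3_class(ens, "nata_sim_ensemble")
  expect_length(ens$final_mean_by_run, 3)
  expect_equal(ens$final_mean, mean(ens$final_mean_by_run))
  expect_length(ens$attributed, 1200)
  single <- simulate_cohort(tr, sim_config(patients = 400, seed = 8))
  expect_equal(ens$final_mean_by_run[1], single$final_mean)
})

test_that("configuration is validated", {
  expect_error(sim_config(timestep = 7), "divide 24")
  expect_error(sim_config(patients = 0), "patients")
})
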