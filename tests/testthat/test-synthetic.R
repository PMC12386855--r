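test_that("hatch_under_treatment inverts the competitiveness estimator", {
  # hand inversion of the Cp formula: 0.936 / (1 + 0.125 * 5) = 0.936/1.625
  expect_equal(hatch_under_treatment(0.936, 0.125, 5), 0.936 / 1.625)
  expect_equal(hatch_under_treatment(0.936, 0.125, 5), 0.576)
  expect_equal(hatch_under_treatment(0.936, 0.7, 0), 0.936)
  expect_equal(hatch_under_treatment(0.936, 0, 5), 0.936)
  expect_error(hatch_under_treatment(0.936, -0.1, 5))
  expect_error(hatch_under_treatment(0.936, 0.1, -5))
  expect_error(hatch_under_treatment(0, 0.1, 5))
  # inversion property over a parameter sweep, machine precision
  set.seed(42)
  for (k in 1:50) {
    p <- runif(1, 0.05, 1)
    cp <- runif(1, 0, 2)
    r <- runif(1, 0.2, 10)
    expect_equal(competitiveness_plugin(p, hatch_under_treatment(p, cp, r), r),
                 cp, tolerance = 1e-12)
  }
})

test_that("emergence inhibition passes through both anchors exactly", {
  expect_equal(emergence_inhibition(0.20, 0.20, 0.67), 0.50)
  expect_equal(emergence_inhibition(0.67, 0.20, 0.67), 0.95)
  expect_identical(emergence_inhibition(0, 0.20, 0.67), 0)
  # slope solved numerically from the two anchor equations:
  # plogis(log(c/ei50)/s) = q  =>  s = log(ei95/ei50)/qlogis(0.95)
  s_oracle <- uniroot(function(s)
    plogis(log(0.67 / 0.20) / s) - 0.95, c(0.1, 2), tol = 1e-12)$root
  expect_equal(log(0.67 / 0.20) / qlogis(0.95), s_oracle, tolerance = 1e-9)
  expect_equal(s_oracle, 0.4106, tolerance = 1e-4)
  # strictly increasing in concentration
  cc <- seq(0.01, 5, by = 0.01)
  expect_true(all(diff(emergence_inhibition(cc)) > 0))
  expect_error(emergence_inhibition(-1))
  expect_error(emergence_inhibition(1, 0.7, 0.2))
})

test_that("simulate_cohort honours corner-case hazards", {
  p0 <- generator_params(daily_molt_hazard_larva = 0,
                         daily_death_hazard_larva = 0,
                         daily_molt_hazard_pupa = 0,
                         daily_death_hazard_pupa = 0)
  set.seed(1)
  sim <- simulate_cohort(50, p0, conc_ppb = 0)
  expect_equal(sim$counts$n_meta, 0L)
  expect_equal(sim$counts$censored, 50L)
  expect_equal(nrow(sim$intervals), 0L)
  expect_equal(simulate_cohort(0, generator_params())$counts$e_meta, 0L)
  # molt hazards 1, death hazards 0, EI = 1: everything pupates, emergence
  # fully blocked, blocked pupae tallied as pupal deaths at the horizon.
  # Oracle: exhaustive enumeration of the chain at these corner hazards.
  p1 <- generator_params(daily_molt_hazard_larva = 1,
                         daily_death_hazard_larva = 0,
                         daily_molt_hazard_pupa = 1,
                         daily_death_hazard_pupa = 0,
                         ei50_ppb = 1e-9, ei95_ppb = 2e-9)  # EI(1) = 1-eps
  oracle <- enumerate_two_stage(1, 0, 1, 0, ei = 1, horizon = 15)
  expect_equal(oracle$p_ndeath, 1)
  expect_equal(oracle$p_emerge, 0)
  set.seed(1)
  sim <- simulate_cohort(40, p1, conc_ppb = 1)
  expect_equal(sim$counts$l_death, 0L)
  expect_equal(sim$counts$n_meta, 0L)
  expect_equal(sim$counts$n_death, 40L)
  expect_equal(sim$counts$censored, 0L)
})

test_that("cohort conservation holds in every simulated cohort", {
  params <- generator_params()
  set.seed(9)
  for (k in 1:20) {
    n <- sample(0:300, 1)
    conc <- sample(c(0, 0.1, 0.5, 3), 1)
    sim <- simulate_cohort(n, params, conc_ppb = conc)
    with(sim$counts,
         expect_equal(n_meta + l_death + n_death + censored, e_meta))
    expect_equal(sim$counts$e_meta, n)
    # aggregating the interval records reproduces the tallies
    if (nrow(sim$intervals) > 0) {
      expect_equal(sum(sim$intervals$deaths[sim$intervals$stage == "larva"]),
                   sim$counts$l_death)
      expect_equal(sum(sim$intervals$molts[sim$intervals$stage == "pupa"]),
                   sim$counts$n_meta)
    }
  }
})

test_that("with negligible inhibition the cohort ignores concentration", {
  params <- generator_params(ei50_ppb = 1e9, ei95_ppb = 2e9)
  set.seed(123)
  a <- simulate_cohort(200, params, conc_ppb = 0)
  set.seed(123)
  b <- simulate_cohort(200, params, conc_ppb = 0.5)
  expect_equal(a$counts, b$counts)
})

test_that("simulated hatch fractions converge on hatch_under_treatment", {
  # law-of-large-numbers check: no cage noise, huge egg counts
  params <- generator_params(sigma_cage = 0, eggs_per_cage_mean = 20000,
                             eggs_dispersion = 1e6)
  trial <- simulate_trial(params = params, seed = 5)
  agg <- aggregate(cbind(eggs_hatched, eggs_total) ~ treatment,
                   data = trial$cohorts, FUN = sum)
  for (j in seq_len(nrow(agg))) {
    tr <- agg$treatment[j]
    cp <- if (tr == "control") 0 else params$cp_by_treatment[[tr]]
    p_true <- hatch_under_treatment(0.936, cp, treatment_s2f(tr))
    p_hat <- agg$eggs_hatched[j] / agg$eggs_total[j]
    se <- sqrt(p_true * (1 - p_true) / agg$eggs_total[j])
    expect_lt(abs(p_hat - p_true), 3 * se + 1e-12)
  }
})

test_that("simulate_trial is deterministic and stable under cage addition", {
  a <- simulate_trial(seed = 3)
  b <- simulate_trial(seed = 3)
  expect_identical(a$cohorts, b$cohorts)
  expect_identical(a$intervals, b$intervals)
  expect_identical(a$water, b$water)
  # control cages never see pyriproxyfen; boosted-only positivity
  w <- a$water
  expect_true(all(w$concentration_ppb[w$dose_mg_per_200 == 0] == 0))
  # adding a replicate leaves the first 20 cages' substreams untouched
  big <- simulate_trial(design = canonical_design(replicates = 5), seed = 3)
  expect_equal(big$cohorts[1:20, ], a$cohorts[1:20, ])
})

test_that("generator parameter validation rejects bad worlds", {
  expect_error(generator_params(ei50_ppb = 0.7, ei95_ppb = 0.2))
  expect_error(generator_params(ph_control = 0))
  expect_error(generator_params(daily_molt_hazard_larva = 1.2))
  expect_error(generator_params(cp_by_treatment = list(SIT1 = -1)))
})
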