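test_that("the zero state is absorbing and seeds reproduce trajectories", {
  pr <- drive_params(h = 1, p = 0.5)
  zero <- integer_state()
  set.seed(99)
  expect_equal(total_queens(stochastic_step(zero, pr)), 0)

  st <- integer_state(q_ww_w = 1200, q_ii_w = 100)
  e1 <- stochastic_simulate(st, pr, 10, replicates = 2, seed = 7)
  e2 <- stochastic_simulate(st, pr, 10, replicates = 2, seed = 7)
  expect_identical(e1$trajectories, e2$trajectories)
  e3 <- stochastic_simulate(st, pr, 10, replicates = 2, seed = 8)
  expect_false(identical(e1$trajectories, e3$trajectories))
})

test_that("one stochastic step agrees with the deterministic step in mean", {
  pr <- drive_params(h = 0.8, p = 0.4)
  st_i <- integer_state(q_ww_w = 1200, q_ww_i = 60, q_wi_w = 60,
                        q_ii_w = 46)
  st_d <- population_state(q_ww_w = 1200, q_ww_i = 60, q_wi_w = 60,
                           q_ii_w = 46)
  det <- total_queens(step_generation(st_d, pr))
  set.seed(123)
  totals <- replicate(1000, total_queens(stochastic_step(st_i, pr)))
  se <- stats::sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - det), 3 * se + 0.02 * det)
})

test_that("drift moves allele frequency where the deterministic twin is static", {
  pr <- drive_params(h = 1, p = 1, c = 1)
  st <- integer_state(q_ww_w = 40, q_ii_w = 10)
  ens <- stochastic_simulate(st, pr, 15, replicates = 30, seed = 21)
  final <- ens$trajectories[ens$trajectories$generation == 15, ]
  expect_gt(stats::var(final$allele_frequency), 0)
  # deterministic twin: allele frequency frozen
  tr <- simulate_drive(population_state(q_ww_w = 40, q_ii_w = 10), pr, 15)
  expect_equal(stats::var(tr$allele_frequency), 0, tolerance = 1e-20)
})

test_that("large-population ensembles track the deterministic trajectory", {
  pr <- drive_params(h = 1, p = 0, c = 1)
  st_i <- integer_state(q_ww_w = 10000, q_ii_w = 700)
  st_d <- population_state(q_ww_w = 10000, q_ii_w = 700)
  gens <- 12
  ens <- stochastic_simulate(st_i, pr, gens, replicates = 40, seed = 5)
  det <- simulate_drive(st_d, pr, gens)
  mean_cf <- ens$summary$mean_carrier_fraction
  expect_true(all(abs(mean_cf - det$carrier_fraction) < 0.02))
})

test_that("interventions apply to the integer engine", {
  pr <- drive_params(h = 1, p = 1)
  st <- integer_state(q_ww_w = 1366)
  sch <- intervention_schedule(cull_event(at = 0, fraction = 1),
                               release_event(at = 0, density = 100))
  ens <- stochastic_simulate(st, pr, 3, replicates = 1, seed = 3,
                             schedule = sch)
  first <- ens$trajectories[1, ]
  expect_equal(first$q_ww_w, 0)
  expect_equal(first$q_ii_w, 100)
})
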