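test_that("closed-form wild-type equilibrium matches fixed-point iteration", {
  pr <- drive_params()
  cf <- wt_equilibrium(pr)
  expect_equal(cf, 1500 * (11.2 - 1) / 11.2, tolerance = 1e-12)
  it <- wt_equilibrium(pr, method = "iterate", tol = 1e-12)
  expect_equal(it, cf, tolerance = 1e-9)
  # sub-replacement populations have no positive equilibrium
  expect_equal(wt_equilibrium(drive_params(s = 0.001)), 0)
})

test_that("critical carrier fraction matches closed form and a grid scan", {
  pr <- drive_params(p = 1)
  d <- critical_carrier_fraction(pr)
  expect_equal(d, (1 - 1 / 11.2)^(1 / 2.5), tolerance = 1e-12)
  expect_gte(d, 0.96)
  expect_equal(critical_carrier_fraction(drive_params(p = 1, m = 1)),
               1 - 1 / 11.2, tolerance = 1e-12)
  # brute-force oracle: scan the low-density growth factor on a fine grid
  grid <- seq(0, 1, by = 1e-4)
  growth <- 11.2 * (1 - grid^2.5)
  oracle <- grid[which(growth < 1)[1]]
  expect_equal(d, oracle, tolerance = 2e-4)
  # with a sperm-load effect the threshold drops (root-found branch)
  d1 <- critical_carrier_fraction(drive_params(p = 1, b = 1))
  growth1 <- 11.2 * (1 - grid^2.5) * (1 - grid)
  expect_equal(d1, grid[which(growth1 < 1)[1]], tolerance = 2e-4)
  expect_lt(d1, d)
  # extreme polyandry pushes the threshold to 1
  expect_gt(critical_carrier_fraction(drive_params(p = 1, m = 500)), 0.999)
  expect_equal(critical_carrier_fraction(drive_params(p = 1, s = 0.001)), 0)
})

test_that("forced-fraction equilibria interpolate between extremes", {
  pr <- drive_params(h = 1, p = 1)
  expect_identical(forced_fraction_equilibrium(0, pr), wt_equilibrium(pr))
  dstar <- critical_carrier_fraction(pr)
  expect_equal(forced_fraction_equilibrium(min(1, dstar + 0.01), pr), 0)
  expect_equal(forced_fraction_equilibrium(1, pr), 0)
  dens <- vapply(seq(0, 1, by = 0.1), forced_fraction_equilibrium,
                 numeric(1), params = pr)
  expect_true(all(diff(dens) <= 1e-6))
})

test_that("infiltration time uses first-passage conventions", {
  pr <- drive_params()
  tr <- simulate_drive(wt_state(pr), pr, 10)
  expect_true(is.na(infiltration_time(tr, 0.5)))
  pr2 <- drive_params(h = 1)
  tr2 <- simulate_drive(wt_state(pr2), pr2, 10,
                        schedule = intervention_schedule(release_event()))
  expect_equal(infiltration_time(tr2, 0), 0)
  expect_equal(infiltration_time(tr2, 0.99), 10)
})

test_that("suppression metrics classify the headline outcomes", {
  pr <- drive_params()
  base <- wt_equilibrium(pr)
  wt <- simulate_drive(wt_state(pr), pr, 30)
  m <- suppression_metrics(wt, base)
  expect_equal(m$suppression_pct, 0, tolerance = 1e-6)
  expect_false(m$eradicated)
  # complete-sterility drive with perfect homing: persists, no suppression
  pr2 <- drive_params(h = 1, p = 1)
  tr2 <- simulate_drive(wt_state(pr2), pr2, 60,
                        schedule = intervention_schedule(release_event()))
  m2 <- suppression_metrics(tr2, base)
  expect_false(m2$eradicated)
  expect_lt(abs(m2$suppression_pct), 10)
  expect_gt(tr2$carrier_fraction[61], 0.01)
})

test_that("phase scans recover the expected outcome structure", {
  pr <- drive_params()
  sc <- phase_scan(pr, h = c(0.5, 1), p = c(0, 0.5, 0.85), horizon = 200L)
  expect_equal(nrow(sc), 6)
  # neutral column: the drive spreads and nothing is suppressed
  neutral <- sc[sc$p == 0, ]
  expect_true(all(neutral$spread))
  expect_true(all(abs(neutral$suppression_pct) < 1))
  expect_false(any(neutral$eradicated))
  # strong sterility with perfect homing eradicates within two centuries
  cell <- sc[sc$h == 1 & sc$p == 0.85, ]
  expect_true(cell$eradicated)
  expect_true(cell$spread)
  expect_equal(cell$suppression_pct, 100)
  # eradication classification robust to halving the threshold
  pr_half <- pr; pr_half$quasi_extinction <- 0.5
  sc_half <- phase_scan(pr_half, h = c(0.5, 1), p = c(0, 0.5, 0.85),
                        horizon = 200L)
  expect_equal(sc_half$eradicated, sc$eradicated)
  gl <- glance(sc)
  expect_equal(gl$p_min_eradication, 0.85)
})
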