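test_that("releases are additive and culls multiplicative", {
  st <- wt_state(drive_params(), density = 1350)
  expect_equal(apply_release(st, 0), st)
  r <- apply_release(st, 100)
  expect_equal(r$q_ii_w, 100)
  expect_equal(total_queens(r), 1450)
  # two releases of 50 equal one of 100
  expect_equal(apply_release(apply_release(st, 50), 50), r)
  expect_error(apply_release(st, 10, class = "q_xx_y"), "unknown release")

  expect_equal(apply_cull(st, 0), st)
  expect_equal(total_queens(apply_cull(st, 1)), 0)
  expect_equal(apply_cull(st, 0.95)$q_ww_w, 67.5)
  # culls commute with themselves
  expect_equal(apply_cull(apply_cull(r, 0.4), 0.6),
               apply_cull(apply_cull(r, 0.6), 0.4))
  expect_error(apply_cull(st, 1.1), "kill_fraction")
})

test_that("schedules unroll with culls ordered before releases", {
  sch <- intervention_schedule(release_event(at = 0, density = 100,
                                             every = 10))
  ev <- expand_schedule(sch, 35)
  expect_equal(ev$generation, c(0L, 10L, 20L, 30L))
  expect_equal(expand_schedule(NULL, 10),
               expand_schedule(intervention_schedule(), 10))
  expect_equal(nrow(expand_schedule(intervention_schedule(), 10)), 0)

  both <- intervention_schedule(
    release_event(at = 5, density = 100),
    cull_event(at = 5, fraction = 0.95))
  ev <- expand_schedule(both, 10)
  expect_equal(ev$kind, c("cull", "release"))
  # released queens are added after the cull, so they are not poisoned
  pr <- drive_params(h = 1, p = 1)
  tr <- simulate_drive(wt_state(pr), pr, 6, schedule = both)
  expect_equal(tr$q_ii_w[6], 100)
})

test_that("populations quickly recover from a cull-only programme", {
  pr <- drive_params()
  q0 <- wt_equilibrium(pr)
  tr <- simulate_drive(wt_state(pr), pr, 15,
                       schedule = intervention_schedule(
                         cull_event(at = 0, fraction = 0.95)))
  # back to within 1% of equilibrium well before the horizon
  rec <- which(abs(tr$total - q0) / q0 < 0.01)
  expect_true(length(rec) > 0 && min(tr$generation[rec]) <= 10)
  expect_equal(tr$total[16], q0, tolerance = 1e-3)
})
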