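pr0 <- drive_params()

test_that("drone pool weights heterozygous queens by one half", {
  d <- drone_pool(population_state(q_ww_w = 1350))
  expect_equal(unlist(d), c(d_w = 1350, d_i = 0))
  d <- drone_pool(population_state(q_wi_w = 10))
  expect_equal(unlist(d), c(d_w = 5, d_i = 5))
  d <- drone_pool(population_state(q_ww_i = 100, q_ii_w = 50))
  expect_equal(unlist(d), c(d_w = 100, d_i = 50))
  expect_equal(unlist(drone_pool(population_state())), c(d_w = 0, d_i = 0))
})

test_that("fertilisation probability follows the polyandry formula", {
  pool <- function(w, i) tibble::tibble(d_w = w, d_i = i)
  # no carrier drones, or fully fertile carriers: every gyne is fertilised
  expect_equal(fertilisation_probability(pool(50, 0), drive_params(p = 1)), 1)
  expect_equal(fertilisation_probability(pool(5, 95), drive_params(p = 0)), 1)
  # equal pools, sterile carriers: f = 1 - 0.5^2.5
  f <- fertilisation_probability(pool(10, 10), drive_params(p = 1))
  expect_equal(f, 1 - 0.5^2.5, tolerance = 1e-12)
  expect_equal(f, 0.8232233, tolerance = 1e-6)
  # bracketing oracle: enumeration at integer mate numbers m = 2 and 3
  lo <- fert_prob_enum(10, 10, p = 1, c = 1, m = 2)
  hi <- fert_prob_enum(10, 10, p = 1, c = 1, m = 3)
  expect_gt(f, lo)
  expect_lt(f, hi)
  # fractional m agrees with the enumeration oracle at integer m
  for (mm in c(2, 3)) {
    expect_equal(
      fertilisation_probability(pool(7, 3), drive_params(p = 0.6, c = 0.8,
                                                         m = mm)),
      fert_prob_enum(7, 3, p = 0.6, c = 0.8, m = mm), tolerance = 1e-12)
  }
  # empty pool: no gyne can be fertilised
  expect_warning(f0 <- fertilisation_probability(pool(0, 0), pr0),
                 "no drones")
  expect_equal(f0, 0)
})

test_that("wild-type transmission weights carrier sperm by c(1-p)", {
  pool <- function(w, i) tibble::tibble(d_w = w, d_i = i)
  expect_equal(wt_transmission(pool(10, 0), pr0), 1)
  expect_equal(wt_transmission(pool(10, 99), drive_params(p = 1)), 1)
  expect_equal(wt_transmission(pool(10, 10), drive_params(p = 0.5)), 2 / 3)
  # weighted-fraction oracle over a finite enumerated pool
  dw <- 12; di <- 8; p <- 0.3; c <- 0.7
  expect_equal(wt_transmission(pool(dw, di), drive_params(p = p, c = c)),
               dw / (dw + c * (1 - p) * di), tolerance = 1e-12)
  # no viable sperm at all: conventional 1
  expect_equal(wt_transmission(pool(0, 10), drive_params(p = 1)), 1)
})

test_that("sperm load is the viable fraction of collected sperm", {
  pool <- function(w, i) tibble::tibble(d_w = w, d_i = i)
  expect_equal(sperm_load(pool(10, 0), drive_params(p = 1)), 1)
  expect_equal(sperm_load(pool(3, 17), drive_params(p = 0)), 1)
  expect_equal(sperm_load(pool(10, 10), drive_params(p = 1)), 0.5)
  expect_equal(sperm_load(pool(0, 0), drive_params(p = 1)), 1)
})

test_that("gyne production discounts carrier-mated queens by (1 - p)", {
  st <- population_state(q_ww_w = 1350)
  expect_equal(gyne_production(st, pr0), 560 * 1350)
  only_i <- population_state(q_ww_i = 10, q_wi_i = 5, q_ii_i = 3)
  expect_equal(gyne_production(only_i, drive_params(p = 1)), 0)
  # with b = 0 the stored sperm load has no effect
  st_lo <- population_state(q_ww_w = 100, z = 0.2)
  st_hi <- population_state(q_ww_w = 100, z = 1)
  expect_equal(gyne_production(st_lo, pr0), gyne_production(st_hi, pr0))
  # with b = 1 it scales linearly
  expect_equal(gyne_production(st_lo, drive_params(b = 1)),
               0.2 * gyne_production(st_hi, drive_params(b = 1)))
})

test_that("winter survival saturates with gyne density", {
  expect_equal(survival_factor(0, pr0), 0.02)
  expect_equal(survival_factor(1500 / 0.02, pr0), 0.01)  # half-saturation
  expect_equal(survival_factor(756000, pr0), 0.02 / 11.08, tolerance = 1e-12)
})

test_that("the annual step fixes the wild-type equilibrium and zero state", {
  zero <- population_state()
  expect_equal(total_queens(step_generation(zero, pr0)), 0)
  qstar <- 1500 * (0.02 * 560 - 1) / (0.02 * 560)
  nxt <- step_generation(population_state(q_ww_w = qstar), pr0)
  expect_equal(nxt$q_ww_w, qstar, tolerance = 1e-12)
  expect_equal(total_queens(nxt), qstar, tolerance = 1e-12)
})

test_that("every step conserves f * g * SigmaG and the mate-class ratio", {
  set.seed(11)
  for (i in 1:25) {
    cs <- random_case()
    st <- cs$state; pr <- cs$params
    d <- drone_pool(st)
    f <- suppressWarnings(fertilisation_probability(d, pr))
    j <- wt_transmission(d, pr)
    g <- survival_factor(gyne_production(st, pr), pr)
    nxt <- step_generation(st, pr)
    expect_equal(total_queens(nxt), f * g * gyne_production(st, pr),
                 tolerance = 1e-12)
    if (j > 0 && j < 1) {
      for (geno in c("ww", "wi", "ii")) {
        qw <- nxt[[paste0("q_", geno, "_w")]]
        qi <- nxt[[paste0("q_", geno, "_i")]]
        if (qw > 0) expect_equal(qi / qw, (1 - j) / j, tolerance = 1e-9)
      }
    }
    expect_true(all(unlist(nxt[1, queen_classes()]) >= 0))
    expect_true(all(is.finite(unlist(nxt[1, queen_classes()]))))
  }
})

test_that("a fitness-neutral drive never loses allele frequency", {
  # mate classes are stored from the previous autumn, so the generation
  # right after a release re-equilibrates them; monotonicity holds from
  # the first self-consistent census onwards
  pr <- drive_params(h = 0.6, p = 0, c = 1)
  st <- population_state(q_ww_w = 1200, q_ii_w = 80)
  tr <- simulate_drive(st, pr, 30)
  expect_true(all(diff(tr$allele_frequency[-1]) >= -1e-12))
  expect_gt(tr$allele_frequency[31], tr$allele_frequency[1])
})

test_that("complete sterility with perfect homing freezes allele frequency", {
  pr <- drive_params(h = 1, p = 1, c = 1)
  st <- population_state(q_ww_w = 900, q_wi_w = 200, q_ii_w = 150,
                         q_ww_i = 50, q_wi_i = 30, q_ii_i = 20)
  tr <- simulate_drive(st, pr, 25)
  # constant from the first census whose mate classes the model assigned
  expect_equal(tr$allele_frequency[-1],
               rep(tr$allele_frequency[2], 25), tolerance = 1e-9)
})

test_that("sterility cassettes are lost without (sufficient) homing", {
  # plain sterility gene, no drive: quickly lost
  tr <- simulate_drive(population_state(q_ww_w = 1366, q_ii_w = 100),
                       drive_params(h = 0, p = 1), 50)
  expect_lt(tr$carrier_fraction[51], 1e-6)
  # complete sterility with imperfect homing: carriers decline to zero
  tr <- simulate_drive(population_state(q_ww_w = 1366, q_ii_w = 100),
                       drive_params(h = 0.8, p = 1), 200)
  expect_lt(tr$carrier_fraction[201], 1e-4)
  expect_true(all(diff(tr$carrier_fraction[50:201]) <= 1e-12))
})
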