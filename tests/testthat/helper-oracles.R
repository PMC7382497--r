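# Independent oracles and fixture generators shared across tests.

# Reduced two-variable map for the perfect-homing, fitness-neutral drive
# (h = 1, p = 0, c = 1): u = carrier-queen fraction, w = fraction of queens
# whose stored mate is a carrier drone. Because a queen's mate class is
# fixed at the previous autumn's mating, paternal drive alleles enter queen
# genotypes one generation after they appear in the drone pool:
#   u' = 1 - (1 - u)(1 - w),   w' = u
# Derived by hand from the six-class recursion; independent of step_q().
neutral_sweep_oracle <- function(u0, generations) {
  u <- u0; w <- 0
  out <- numeric(generations + 1)
  out[1] <- u
  for (t in seq_len(generations)) {
    u_new <- 1 - (1 - u) * (1 - w)
    w <- u
    u <- u_new
    out[t + 1] <- u
  }
  out
}

# Enumerates a gyne's matings over all 2^m drone-type combinations to get
# the fertilisation probability for integer m (each mating independently
# hits a carrier with the competitiveness-weighted probability).
fert_prob_enum <- function(d_w, d_i, p, c, m) {
  pi_carrier <- c * d_i / (d_w + c * d_i)
  fail_all <- 0
  # enumerate every carrier/wild pattern of the m matings; a pattern leaves
  # the gyne unfertilised only if every mating is with a carrier AND sterile
  for (pattern in 0:(2^m - 1)) {
    carriers <- sum(bitwAnd(pattern, 2^(0:(m - 1))) > 0)
    prob_pattern <- pi_carrier^carriers * (1 - pi_carrier)^(m - carriers)
    if (carriers == m) fail_all <- fail_all + prob_pattern * p^m
  }
  1 - fail_all
}

# A random valid census + parameter set (used for property sweeps).
random_case <- function() {
  q <- stats::runif(6, 0, 2000) * stats::rbinom(6, 1, 0.7)
  st <- population_state(q[1], q[2], q[3], q[4], q[5], q[6],
                         z = stats::runif(1),
                         generation = sample(0:10, 1))
  pr <- drive_params(h = stats::runif(1), p = stats::runif(1),
                     c = stats::runif(1), m = stats::runif(1, 0.5, 5),
                     s = stats::runif(1, 0.005, 0.5),
                     n = stats::runif(1, 100, 5000),
                     lambda = stats::runif(1, 10, 1000),
                     b = sample(c(0, 0.5, 1, 2), 1))
  list(state = st, params = pr)
}
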