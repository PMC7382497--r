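#' @title Deterministic annual recursion
#' @description
#' The model follows the *Vespula* colony cycle on a yearly time step.
#' Summer queen density (= nest density) `Q` is classified by queen genotype
#' (`ww`, `wi`, `ii`) and the genotype of the effective mate (`w`, `i`),
#' giving six classes. Each year: nests produce gynes and drones in autumn,
#' gynes mate at random with the mixed drone pool, a fraction survive winter
#' under density-dependent nest-site competition, and the survivors found
#' next summer's nests. All intermediate quantities (drone pool, the
#' fertilisation probability `f`, the wild-type transmission share `j`, the
#' sperm-load factor `Z`, gyne output and the survival factor `g`) are
#' exposed as separately testable functions.
#' @name model_core
NULL

# ---------------------------------------------------------------------------
# internal scalar kernels: operate on plain numerics, used by both engines

drones_of <- function(q) {
  c(d_w = q[[1]] + q[[2]] + 0.5 * (q[[3]] + q[[4]]),
    d_i = 0.5 * (q[[3]] + q[[4]]) + q[[5]] + q[[6]])
}

fert_prob <- function(d_w, d_i, p, c, m, warn = FALSE) {
  den <- d_w + c * d_i
  if (den <= 0) {
    if (warn) warning("no drones available: no gyne can be fertilised (f = 0)",
                      call. = FALSE)
    return(0)
  }
  1 - (p * c * d_i / den)^m
}

wt_share <- function(d_w, d_i, p, c) {
  den <- d_w + c * (1 - p) * d_i
  if (den <= 0) return(1)  # no viable sperm at all; the split multiplies zero
  d_w / den
}

sperm_load_of <- function(d_w, d_i, p, c) {
  den <- d_w + c * d_i
  if (den <= 0) return(1)  # no mating occurred; moot because f = 0
  (d_w + c * (1 - p) * d_i) / den
}

gynes_of <- function(q, z, p, lambda, b) {
  lambda * z^b * (q[[1]] + q[[3]] + q[[5]] +
                    (1 - p) * (q[[2]] + q[[4]] + q[[6]]))
}

survival_of <- function(sigma_g, s, n) {
  s / (1 + s * sigma_g / n)
}

# one deterministic step on a raw class vector; returns list(q, z, f, j, g,
# sigma_g) where q/z are next summer's census and f/j/g/sigma_g are the
# transition quantities computed from the current state
step_q <- function(q, z, pr) {
  d <- drones_of(q)
  sigma_g <- gynes_of(q, z, pr$p, pr$lambda, pr$b)
  f <- fert_prob(d[[1]], d[[2]], pr$p, pr$c, pr$m)
  j <- wt_share(d[[1]], d[[2]], pr$p, pr$c)
  z_next <- sperm_load_of(d[[1]], d[[2]], pr$p, pr$c)
  g <- survival_of(sigma_g, pr$s, pr$n)
  amp <- pr$lambda * z^pr$b * f * g
  h <- pr$h; p <- pr$p
  b_ww <- q[[1]] + 0.5 * q[[3]]
  b_wi <- (1 - h) * ((1 - p) * (q[[2]] + 0.5 * q[[4]]) + 0.5 * q[[3]] + q[[5]])
  b_ii <- (1 - p) * (h * q[[2]] + 0.5 * (1 + h) * q[[4]] + q[[6]]) +
    h * (0.5 * q[[3]] + q[[5]])
  prod <- amp * c(b_ww, b_wi, b_ii)
  q_next <- c(j * prod[[1]], (1 - j) * prod[[1]],
              j * prod[[2]], (1 - j) * prod[[2]],
              j * prod[[3]], (1 - j) * prod[[3]])
  names(q_next) <- queen_classes()
  list(q = q_next, z = z_next, f = f, j = j, g = g, sigma_g = sigma_g)
}

# ---------------------------------------------------------------------------
# exported operations

#' Autumn drone pool produced by a summer census
#'
#' Drones develop from unfertilised eggs and carry their mother's allele:
#' `ww` queens contribute only wild-type drones, `ii` queens only carrier
#' drones, and `wi` queens contribute half each. Only the ratio of the two
#' drone densities matters downstream, so the proportionality constant is 1.
#'
#' @param state A [population_state()].
#' @return A one-row tibble with columns `d_w`, `d_i`.
#' @export
drone_pool <- function(state) {
  d <- drones_of(state_q(state))
  tibble::tibble(d_w = d[[1]], d_i = d[[2]])
}

#' Probability that a gyne is successfully fertilised
#'
#' A gyne mates with `m` drones on average; a mating with a carrier drone
#' fails to transfer viable sperm with probability `p`. Fertilisation fails
#' only if every mating fails, so
#' `f = 1 - (p c D_i / (D_w + c D_i))^m`.
#' With no drones at all, `f = 0` (and a warning is emitted).
#'
#' @param drones A drone pool (tibble with `d_w`, `d_i`) from
#'   [drone_pool()].
#' @param params A [drive_params()].
#' @return Probability in `[0, 1]`.
#' @export
fertilisation_probability <- function(drones, params) {
  fert_prob(drones$d_w, drones$d_i, params$p, params$c, params$m, warn = TRUE)
}

#' Share of fertile matings transmitting the wild-type allele
#'
#' Among matings that transfer viable sperm, the wild-type share is
#' `j = D_w / (D_w + c (1 - p) D_i)`. When no viable sperm exists at all
#' the convention `j = 1` is returned; the value is then multiplied by a
#' zero production term in the recursion.
#'
#' @inheritParams fertilisation_probability
#' @return Probability in `[0, 1]`.
#' @export
wt_transmission <- function(drones, params) {
  wt_share(drones$d_w, drones$d_i, params$p, params$c)
}

#' Sperm-load factor of the next queen generation
#'
#' The population-level fraction of viable sperm received by the gynes:
#' `Z' = (D_w + c (1 - p) D_i) / (D_w + c D_i)`. Stored on the *next*
#' generation's state; raised to the exponent `b` it scales per-nest gyne
#' output. Returns 1 for an empty drone pool (no mating occurred).
#'
#' @inheritParams fertilisation_probability
#' @return Factor in `[0, 1]`.
#' @export
sperm_load <- function(drones, params) {
  sperm_load_of(drones$d_w, drones$d_i, params$p, params$c)
}

#' Total autumn gyne production
#'
#' `Sigma G = lambda Z^b (Q_ww_w + Q_wi_w + Q_ii_w + (1 - p)(Q_ww_i +
#' Q_wi_i + Q_ii_i))`: queens that carry viable carrier sperm raise smaller
#' broods by the factor `(1 - p)`. Uses the sperm-load factor `z` stored on
#' `state` (the load its queens collected last autumn).
#'
#' @param state A [population_state()].
#' @param params A [drive_params()].
#' @return Gyne density per km^2.
#' @export
gyne_production <- function(state, params) {
  gynes_of(state_q(state), state$z, params$p, params$lambda, params$b)
}

#' Density-dependent winter survival factor
#'
#' A proportion `s` of gynes survive winter and then compete for nest
#' sites: `g = s / (1 + s SigmaG / n)`. Unmated queens take part in the
#' competition too, so `sigma_g` must be *total* gyne production; the
#' fertilisation probability `f` is applied separately in the recursion.
#'
#' @param sigma_g Total gyne density per km^2 (see [gyne_production()]).
#' @param params A [drive_params()].
#' @return Survival factor in `(0, s]`.
#' @export
survival_factor <- function(sigma_g, params) {
  stopifnot(sigma_g >= 0)
  survival_of(sigma_g, params$s, params$n)
}

#' Advance the census by one year
#'
#' Applies the full annual recursion: gyne production (using the state's
#' stored sperm load), drone production, random mating (`f`, `j`, next
#' `Z`), and density-dependent establishment (`g`). Genotype production is
#' computed first (with homing moving a fraction `h` of heterozygous
#' offspring to the homozygous class) and then split into mate classes by
#' the factors `j` and `1 - j` — algebraically identical to the
#' `(1 - j)/j` ratio form but defined when `j = 0`.
#'
#' @param state A [population_state()].
#' @param params A [drive_params()].
#' @return Next summer's `population_state` (generation incremented, `z`
#'   replaced by the new sperm load).
#' @examples
#' pr <- drive_params(h = 1)
#' step_generation(wt_state(pr), pr)
#' @export
step_generation <- function(state, params) {
  st <- step_q(state_q(state), state$z, params)
  state_from_q(st$q, st$z, state$generation + 1L)
}
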