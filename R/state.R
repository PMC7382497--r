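#' The six queen-class names, in fixed order
#'
#' A queen class is `q_<genotype>_<mate>`: the queen's diploid genotype
#' (`ww`, `wi`, `ii`; `w` = wild-type allele, `i` = drive allele) crossed
#' with the haploid genotype of the drone sperm she effectively carries
#' (`w` or `i`).
#'
#' @return Character vector of the six class names.
#' @export
queen_classes <- function() {
  c("q_ww_w", "q_ww_i", "q_wi_w", "q_wi_i", "q_ii_w", "q_ii_i")
}

#' Construct a summer queen census
#'
#' A population state is the summer census of founding queens (one nest per
#' queen): densities of the six queen classes, the sperm-load factor `z`
#' carried over from last autumn's matings, and the generation index
#' (one generation = one year).
#'
#' @param q_ww_w,q_ww_i,q_wi_w,q_wi_i,q_ii_w,q_ii_i Queen (= nest)
#'   densities per km^2 by genotype x mate class. All `>= 0`.
#' @param z Sperm-load factor of this queen generation, in `[0, 1]`;
#'   1 for an all-wild-type founding state.
#' @param generation Integer time index. Default 0.
#'
#' @return A one-row tibble of class `population_state`.
#' @examples
#' population_state(q_ww_w = 1350)
#' @export
population_state <- function(q_ww_w = 0, q_ww_i = 0, q_wi_w = 0, q_wi_i = 0,
                             q_ii_w = 0, q_ii_i = 0, z = 1, generation = 0L) {
  q <- c(q_ww_w = q_ww_w, q_ww_i = q_ww_i, q_wi_w = q_wi_w,
         q_wi_i = q_wi_i, q_ii_w = q_ii_w, q_ii_i = q_ii_i)
  if (any(!is.finite(q)) || any(q < 0)) {
    stop("queen class densities must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(z) || z < 0 || z > 1) {
    stop("z must be in [0, 1]", call. = FALSE)
  }
  out <- tibble::tibble(
    generation = as.integer(generation),
    q_ww_w = q_ww_w, q_ww_i = q_ww_i, q_wi_w = q_wi_w,
    q_wi_i = q_wi_i, q_ii_w = q_ii_w, q_ii_i = q_ii_i, z = z
  )
  class(out) <- c("population_state", class(out))
  out
}

#' Wild-type population at its demographic equilibrium
#'
#' Convenience constructor: an all-wild-type census at the equilibrium nest
#' density implied by `params` (see [wt_equilibrium()]), or at an explicit
#' density.
#'
#' @param params A [drive_params()] object.
#' @param density Nest density per km^2; defaults to the closed-form
#'   wild-type equilibrium.
#' @return A `population_state`.
#' @export
wt_state <- function(params = drive_params(), density = wt_equilibrium(params)) {
  population_state(q_ww_w = density)
}

# internal: named numeric vector of the six class densities
state_q <- function(state) {
  unlist(state[1, queen_classes()], use.names = TRUE)
}

# internal: rebuild a population_state from a class vector
state_from_q <- function(q, z, generation) {
  population_state(q[[1]], q[[2]], q[[3]], q[[4]], q[[5]], q[[6]],
                   z = z, generation = generation)
}

#' Total queen density of a state
#' @param state A `population_state`.
#' @return Total nests per km^2.
#' @export
total_queens <- function(state) {
  sum(state_q(state))
}

# internal summaries on a raw class vector -----------------------------------

# fraction of queens carrying >= 1 drive allele
carrier_fraction_q <- function(q) {
  tot <- sum(q)
  if (tot <= 0) return(0)
  (tot - q[[1]] - q[[2]]) / tot
}

# frequency of the drive allele among queen genotypes
allele_frequency_q <- function(q) {
  tot <- sum(q)
  if (tot <= 0) return(0)
  (0.5 * (q[[3]] + q[[4]]) + q[[5]] + q[[6]]) / tot
}
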