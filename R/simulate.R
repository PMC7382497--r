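#' Simulate the deterministic model over many generations
#'
#' Iterates the annual recursion from an initial census, applying any
#' scheduled interventions. Within a generation the order is: cull, then
#' release, then the recorded census, then the dynamics step to the next
#' year. The returned trajectory therefore shows post-intervention
#' censuses (a release at generation 0 appears in row 0).
#'
#' @param initial A [population_state()].
#' @param params A [drive_params()].
#' @param generations Number of annual steps, `>= 1`.
#' @param schedule Optional [intervention_schedule()].
#' @return A tibble of class `drive_trajectory` with one row per generation
#'   (`generations + 1` rows): the six queen classes, `total`,
#'   `carrier_fraction` (queens with at least one drive allele),
#'   `allele_frequency` (drive-allele frequency among queen genotypes),
#'   `z`, and the transition quantities `sigma_g`, `f`, `j`, `g` computed
#'   from that row's census, plus an `events` annotation column. The
#'   parameters and schedule are attached as attributes.
#' @examples
#' pr <- drive_params(h = 1, p = 0)
#' tr <- simulate_drive(wt_state(pr), pr, generations = 15,
#'                      schedule = intervention_schedule(release_event()))
#' tr[c("generation", "total", "carrier_fraction")]
#' @export
simulate_drive <- function(initial, params, generations,
                           schedule = NULL) {
  stopifnot(inherits(initial, "population_state"), generations >= 1)
  events <- expand_schedule(schedule, horizon = generations)
  gen0 <- initial$generation
  q <- state_q(initial)
  z <- initial$z
  nrows <- generations + 1L
  cls <- matrix(0, nrows, 6, dimnames = list(NULL, queen_classes()))
  zv <- fv <- jv <- gv <- sg <- numeric(nrows)
  ev <- character(nrows)

  for (row in seq_len(nrows)) {
    gen <- gen0 + row - 1L
    here <- events[events$generation == gen, , drop = FALSE]
    if (nrow(here) > 0) {
      for (k in seq_len(nrow(here))) {
        if (here$kind[k] == "cull") {
          q <- q * (1 - here$magnitude[k])
        } else {
          q[here$class[k]] <- q[here$class[k]] + here$magnitude[k]
        }
      }
      ev[row] <- paste(sprintf("%s(%g)", here$kind, here$magnitude),
                       collapse = "; ")
    }
    st <- step_q(q, z, params)
    cls[row, ] <- q
    zv[row] <- z; fv[row] <- st$f; jv[row] <- st$j
    gv[row] <- st$g; sg[row] <- st$sigma_g
    q <- st$q
    z <- st$z
  }

  tot <- rowSums(cls)
  carrier <- ifelse(tot > 0, (tot - cls[, 1] - cls[, 2]) / tot, 0)
  allele <- ifelse(tot > 0,
                   (0.5 * (cls[, 3] + cls[, 4]) + cls[, 5] + cls[, 6]) / tot,
                   0)
  out <- tibble::tibble(
    generation = gen0 + seq_len(nrows) - 1L,
    q_ww_w = cls[, 1], q_ww_i = cls[, 2], q_wi_w = cls[, 3],
    q_wi_i = cls[, 4], q_ii_w = cls[, 5], q_ii_i = cls[, 6],
    total = tot, carrier_fraction = carrier, allele_frequency = allele,
    z = zv, sigma_g = sg, f = fv, j = jv, g = gv, events = ev
  )
  new_drive_trajectory(out, params, schedule)
}

new_drive_trajectory <- function(df, params, schedule) {
  structure(df,
            class = c("drive_trajectory", class(tibble::tibble())),
            params = params, schedule = schedule)
}

#' @export
print.drive_trajectory <- function(x, ...) {
  pr <- attr(x, "params")
  cat(sprintf(
    "<drive_trajectory> %d generations | h = %g, p = %g, c = %g, b = %g\n",
    max(x$generation) - min(x$generation), pr$h, pr$p, pr$c, pr$b))
  NextMethod()
}

#' Tidy a trajectory into long queen-class format
#'
#' One row per generation x queen class, convenient for ggplot2 stacking.
#'
#' @param x A `drive_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `generation`, `class`, `genotype`,
#'   `mate`, `density`.
#' @export
tidy.drive_trajectory <- function(x, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(x),
                              cols = dplyr::all_of(queen_classes()),
                              names_to = "class", values_to = "density")
  long$genotype <- sub("^q_(ww|wi|ii)_(w|i)$", "\\1", long$class)
  long$mate <- sub("^q_(ww|wi|ii)_(w|i)$", "\\2", long$class)
  long[, c("generation", "class", "genotype", "mate", "density")]
}

#' One-row summary of a trajectory
#'
#' Wraps [suppression_metrics()] with the wild-type equilibrium of the
#' trajectory's own parameters as baseline.
#'
#' @param x A `drive_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble (see [suppression_metrics()]).
#' @export
glance.drive_trajectory <- function(x, ...) {
  suppression_metrics(x, baseline = wt_equilibrium(attr(x, "params")))
}
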