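#' Integer-state stochastic twin of the deterministic model
#'
#' The stochastic engine follows the same annual cycle on whole-queen
#' counts in a fixed area (default 1 km^2), adding demographic
#' stochasticity and gene drift: Poisson brood sizes, random mate numbers
#' (2 or 3, mean 2.5), competitiveness-weighted mate sampling, per-gyne
#' homing conversion, and binomial winter survival. Each random choice
#' mirrors one factor of the deterministic recursion, so expectations
#' agree on large populations.
#'
#' @name stochastic_engine
NULL

#' Construct an integer census
#'
#' @param q_ww_w,q_ww_i,q_wi_w,q_wi_i,q_ii_w,q_ii_i Whole-queen counts
#'   (non-negative integers) by genotype x mate class.
#' @param z Sperm-load factor in `[0, 1]`.
#' @param generation Integer time index.
#' @return A one-row tibble of class `integer_state` (and
#'   `population_state`).
#' @export
integer_state <- function(q_ww_w = 0, q_ww_i = 0, q_wi_w = 0, q_wi_i = 0,
                          q_ii_w = 0, q_ii_i = 0, z = 1, generation = 0L) {
  cnt <- c(q_ww_w, q_ww_i, q_wi_w, q_wi_i, q_ii_w, q_ii_i)
  if (any(cnt != round(cnt))) {
    stop("integer_state requires whole-queen counts", call. = FALSE)
  }
  out <- population_state(q_ww_w, q_ww_i, q_wi_w, q_wi_i, q_ii_w, q_ii_i,
                          z = z, generation = generation)
  class(out) <- c("integer_state", class(out))
  out
}

# one stochastic annual step on a raw integer vector
stoch_step_q <- function(q, z, pr) {
  zero <- list(q = stats::setNames(integer(6), queen_classes()), z = 1)
  if (sum(q) == 0) return(zero)
  d <- drones_of(q)
  d_w <- d[[1]]; d_i <- d[[2]]
  z_next <- sperm_load_of(d_w, d_i, pr$p, pr$c)

  # per-class expected brood; carrier-mated queens raise (1 - p) as much
  brood <- pr$lambda * z^pr$b *
    c(1, 1 - pr$p, 1, 1 - pr$p, 1, 1 - pr$p) * q
  gy <- stats::rpois(6, brood)

  # offspring genotype (ww, wi, ii) per maternal class, homing included
  h <- pr$h
  geno_p <- rbind(
    c(1, 0, 0),                                # ww_w
    c(0, 1 - h, h),                            # ww_i
    c(0.5, 0.5 * (1 - h), 0.5 * h),            # wi_w
    c(0, 0.5 * (1 - h), 0.5 * (1 + h)),        # wi_i
    c(0, 1 - h, h),                            # ii_w
    c(0, 0, 1)                                 # ii_i
  )
  geno <- c(ww = 0L, wi = 0L, ii = 0L)
  for (k in 1:6) {
    if (gy[k] > 0) geno <- geno + drop(stats::rmultinom(1, gy[k], geno_p[k, ]))
  }

  sigma_g <- sum(gy)  # realised total gyne production
  g <- survival_of(sigma_g, pr$s, pr$n)

  den <- d_w + pr$c * d_i
  if (den <= 0) return(zero)         # no drones: nothing gets fertilised
  p_sterile <- pr$p * pr$c * d_i / den  # a mating is carrier and sterile
  j <- wt_share(d_w, d_i, pr$p, pr$c)

  q_next <- stats::setNames(integer(6), queen_classes())
  for (gn in 1:3) {
    ng <- geno[gn]
    if (ng == 0) next
    # each gyne mates 2 or 3 times with equal probability (mean 2.5);
    # she is fertilised unless every mating is sterile
    n3 <- stats::rbinom(1, ng, 0.5)
    n2 <- ng - n3
    fert <- stats::rbinom(1, n2, 1 - p_sterile^2) +
      stats::rbinom(1, n3, 1 - p_sterile^3)
    # effective mate class among the fertilised
    mate_w <- stats::rbinom(1, fert, j)
    mate_i <- fert - mate_w
    # winter survival + nest-site competition at realised gyne density
    iw <- 2L * gn - 1L
    q_next[iw] <- stats::rbinom(1, mate_w, g)
    q_next[iw + 1L] <- stats::rbinom(1, mate_i, g)
  }
  list(q = q_next, z = z_next)
}

#' One stochastic generation
#'
#' Advances an integer census by one year using the engine's sampling
#' scheme. Uses R's global random-number stream; seed with [set.seed()]
#' for reproducibility. The zero state is absorbing.
#'
#' @param state An [integer_state()].
#' @param params A [drive_params()].
#' @return The next year's `integer_state`.
#' @export
stochastic_step <- function(state, params) {
  st <- stoch_step_q(state_q(state), state$z, params)
  out <- integer_state(st$q[[1]], st$q[[2]], st$q[[3]], st$q[[4]],
                       st$q[[5]], st$q[[6]], z = st$z,
                       generation = state$generation + 1L)
  out
}

#' Replicated stochastic simulation
#'
#' Runs `replicates` independent trajectories from the same initial
#' census, each with its own seeded stream (`seed + replicate - 1`), and
#' summarises them. Interventions follow the same within-generation order
#' as the deterministic engine (cull, then release, then census); culls
#' thin each class binomially, releases add whole queens.
#'
#' @param initial An [integer_state()].
#' @param params A [drive_params()].
#' @param generations Annual steps per replicate, `>= 1`.
#' @param replicates Number of replicates, `>= 1`.
#' @param schedule Optional [intervention_schedule()].
#' @param seed Base seed; replicate `r` uses `seed + r - 1`. `NULL` leaves
#'   the global stream untouched (not reproducible).
#' @return A list of class `drive_ensemble`: `trajectories` (tibble with a
#'   `replicate` column; per-generation counts, `total`,
#'   `carrier_fraction`, `allele_frequency`, `z`), `summary`
#'   (per-generation mean/median/5%/95% of total and mean carrier
#'   fraction), and `extinction_probability` (fraction of replicates at
#'   the zero state by the horizon).
#' @export
stochastic_simulate <- function(initial, params, generations,
                                replicates = 1L, schedule = NULL,
                                seed = NULL) {
  stopifnot(inherits(initial, "integer_state"), generations >= 1,
            replicates >= 1)
  events <- expand_schedule(schedule, horizon = generations)
  gen0 <- initial$generation
  run_one <- function(rep_idx) {
    if (!is.null(seed)) set.seed(seed + rep_idx - 1L)
    q <- state_q(initial)
    z <- initial$z
    nrows <- generations + 1L
    cls <- matrix(0L, nrows, 6, dimnames = list(NULL, queen_classes()))
    zv <- numeric(nrows)
    for (row in seq_len(nrows)) {
      gen <- gen0 + row - 1L
      here <- events[events$generation == gen, , drop = FALSE]
      if (nrow(here) > 0) {
        for (k in seq_len(nrow(here))) {
          if (here$kind[k] == "cull") {
            q <- stats::rbinom(6, q, 1 - here$magnitude[k])
            names(q) <- queen_classes()
          } else {
            q[here$class[k]] <- q[here$class[k]] +
              as.integer(round(here$magnitude[k]))
          }
        }
      }
      cls[row, ] <- q
      zv[row] <- z
      if (row < nrows) {
        st <- stoch_step_q(q, z, params)
        q <- st$q; z <- st$z
      }
    }
    tot <- rowSums(cls)
    tibble::tibble(
      replicate = rep_idx,
      generation = gen0 + seq_len(nrows) - 1L,
      q_ww_w = cls[, 1], q_ww_i = cls[, 2], q_wi_w = cls[, 3],
      q_wi_i = cls[, 4], q_ii_w = cls[, 5], q_ii_i = cls[, 6],
      total = tot,
      carrier_fraction = ifelse(tot > 0, (tot - cls[, 1] - cls[, 2]) / tot, 0),
      allele_frequency = ifelse(
        tot > 0, (0.5 * (cls[, 3] + cls[, 4]) + cls[, 5] + cls[, 6]) / tot, 0),
      z = zv
    )
  }
  traj <- dplyr::bind_rows(lapply(seq_len(replicates), run_one))
  summary <- traj |>
    dplyr::group_by(.data$generation) |>
    dplyr::summarise(
      mean_total = mean(.data$total),
      median_total = stats::median(.data$total),
      q05_total = stats::quantile(.data$total, 0.05),
      q95_total = stats::quantile(.data$total, 0.95),
      mean_carrier_fraction = mean(.data$carrier_fraction),
      .groups = "drop"
    )
  final <- traj[traj$generation == max(traj$generation), ]
  structure(
    list(trajectories = traj, summary = summary,
         extinction_probability = mean(final$total == 0),
         params = params, seed = seed, replicates = replicates),
    class = "drive_ensemble"
  )
}

#' @export
print.drive_ensemble <- function(x, ...) {
  cat(sprintf(
    "<drive_ensemble> %d replicates | extinction probability %.3f\n",
    x$replicates, x$extinction_probability))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.drive_ensemble <- function(x, ...) {
  x$trajectories
}

#' @export
glance.drive_ensemble <- function(x, ...) {
  fin <- x$summary[nrow(x$summary), ]
  tibble::tibble(
    replicates = x$replicates,
    generations = max(x$summary$generation) - min(x$summary$generation),
    extinction_probability = x$extinction_probability,
    final_mean_total = fin$mean_total,
    final_mean_carrier_fraction = fin$mean_carrier_fraction
  )
}
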