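#' Wild-type demographic equilibrium
#'
#' With no drive alleles the recursion collapses to the Beverton-Holt-like
#' map `Q' = s lambda Q / (1 + s lambda Q / n)`, whose non-trivial fixed
#' point is `n (s lambda - 1) / (s lambda)` when `s lambda > 1` and 0
#' otherwise. `method = "iterate"` runs the full six-class recursion from a
#' positive all-wild-type start to convergence instead; the two agree to
#' the iteration tolerance.
#'
#' @param params A [drive_params()].
#' @param method `"closed_form"` (default) or `"iterate"`.
#' @param tol Relative convergence tolerance for the iterative method.
#' @param max_iter Iteration cap.
#' @return Equilibrium nest density per km^2.
#' @examples
#' wt_equilibrium(drive_params())  # ~1366 nests per km^2
#' @export
wt_equilibrium <- function(params = drive_params(),
                           method = c("closed_form", "iterate"),
                           tol = 1e-12, max_iter = 10000L) {
  method <- match.arg(method)
  sl <- params$s * params$lambda
  if (sl <= 1) return(0)
  if (method == "closed_form") return(params$n * (sl - 1) / sl)
  q <- c(q_ww_w = 1, q_ww_i = 0, q_wi_w = 0, q_wi_i = 0, q_ii_w = 0,
         q_ii_i = 0)
  z <- 1
  for (iter in seq_len(max_iter)) {
    st <- step_q(q, z, params)
    if (abs(sum(st$q) - sum(q)) <= tol * max(sum(q), 1)) {
      return(sum(st$q))
    }
    q <- st$q; z <- st$z
  }
  warning("wt_equilibrium: iteration did not converge", call. = FALSE)
  sum(q)
}

#' Critical carrier fraction for population collapse
#'
#' For a complete-sterility construct (`p = 1`, `c = 1`), the smallest
#' fraction `d` of carrier queens at which low-density population growth
#' falls below replacement: the growth factor per generation is
#' `s lambda (1 - d^m) (1 - d)^b`, evaluated where nest-site competition
#' vanishes (`g -> s`). With `b = 0` the closed form is
#' `d* = (1 - 1/(s lambda))^(1/m)`; otherwise the root is bracketed
#' numerically to `tol`.
#'
#' @param params A [drive_params()].
#' @param tol Root-finding tolerance (ignored for the closed form).
#' @return The critical fraction in `[0, 1]`; 0 if `s lambda <= 1` (the
#'   population is below replacement with no carriers at all).
#' @examples
#' critical_carrier_fraction(drive_params())  # ~0.963: "at least 96%"
#' @export
critical_carrier_fraction <- function(params = drive_params(), tol = 1e-6) {
  sl <- params$s * params$lambda
  if (sl <= 1) return(0)
  if (params$b == 0) return((1 - 1 / sl)^(1 / params$m))
  growth <- function(d) sl * (1 - d^params$m) * (1 - d)^params$b - 1
  stats::uniroot(growth, c(0, 1), tol = tol)$root
}

#' Long-run density under an exogenously pinned carrier fraction
#'
#' Holds the carrier-queen fraction fixed each generation (rescaling the
#' census after every step while preserving total density and the
#' within-carrier genotype mix) and iterates until the total converges.
#' This models an imposed population composition rather than a dynamic
#' drive outcome; above the critical fraction the population collapses
#' to 0.
#'
#' Because the rescaling preserves the within-carrier genotype mix, the
#' carriers only breed true when heterozygotes are converted (`h = 1`,
#' the default here): without homing the pinned carrier pool drifts to
#' heterozygotes whose drones are half wild-type, which weakens the
#' sterility pressure and decouples the curve from the analytic
#' threshold of [critical_carrier_fraction()].
#'
#' @param carrier_fraction Pinned fraction of carrier queens in `[0, 1]`.
#' @param params A [drive_params()]; the sterility `p`, competitiveness
#'   `c` and sperm-load exponent `b` shape the curve.
#' @param carrier_class Class used to (re)seed carriers; default `q_ii_w`.
#' @param generations Iteration cap.
#' @param tol Relative convergence tolerance on total density.
#' @return Long-run total nest density per km^2 (0 once below the
#'   quasi-extinction threshold).
#' @export
forced_fraction_equilibrium <- function(carrier_fraction,
                                        params = drive_params(h = 1, p = 1),
                                        carrier_class = "q_ii_w",
                                        generations = 2000L, tol = 1e-10) {
  stopifnot(carrier_fraction >= 0, carrier_fraction <= 1)
  d <- carrier_fraction
  if (d == 0) return(wt_equilibrium(params))
  q0 <- wt_equilibrium(params)
  if (q0 <= 0) return(0)
  q <- stats::setNames(numeric(6), queen_classes())
  q["q_ww_w"] <- (1 - d) * q0
  q[carrier_class] <- d * q0
  z <- 1
  icar <- c(3L, 4L, 5L, 6L)  # wi and ii classes
  iwt <- c(1L, 2L)
  for (iter in seq_len(generations)) {
    st <- step_q(q, z, params)
    qn <- st$q
    tot <- sum(qn)
    if (tot < params$quasi_extinction) return(0)
    # re-pin the composition, preserving total density
    car <- sum(qn[icar]); wt <- sum(qn[iwt])
    qp <- qn
    qp[icar] <- if (car > 0) qn[icar] * (d * tot / car) else 0
    if (car <= 0) qp[carrier_class] <- d * tot
    qp[iwt] <- if (wt > 0) qn[iwt] * ((1 - d) * tot / wt) else 0
    if (wt <= 0) qp["q_ww_w"] <- (1 - d) * tot
    if (abs(tot - sum(q)) <= tol * max(sum(q), 1)) return(tot)
    q <- qp; z <- st$z
  }
  sum(q)
}

#' First generation at which the drive reaches a carrier-fraction threshold
#'
#' @param trajectory A `drive_trajectory` (or any tibble with
#'   `generation` and `carrier_fraction` columns).
#' @param threshold Fraction in `[0, 1]`. A threshold of 0 asks for the
#'   first generation with *any* carriers.
#' @return The generation index, or `NA` if never reached.
#' @export
infiltration_time <- function(trajectory, threshold = 0.9) {
  stopifnot(threshold >= 0, threshold <= 1)
  hit <- if (threshold > 0) {
    trajectory$carrier_fraction >= threshold
  } else {
    trajectory$carrier_fraction > 0
  }
  if (!any(hit)) return(NA_integer_)
  trajectory$generation[which(hit)[1]]
}

#' Suppression and eradication metrics of a trajectory
#'
#' @param trajectory A `drive_trajectory`.
#' @param baseline Reference density (> 0), typically [wt_equilibrium()].
#' @param tail_fraction Fraction of final generations averaged as the
#'   "long-run" density. Default 0.1.
#' @return One-row tibble: `min_density`, `longrun_density`,
#'   `suppression_pct` (`100 (1 - longrun/baseline)`), `eradicated`
#'   (density fell below the quasi-extinction threshold), and
#'   `t_eradication` (`NA` if never).
#' @export
suppression_metrics <- function(trajectory, baseline,
                                tail_fraction = 0.1) {
  stopifnot(baseline > 0)
  pr <- attr(trajectory, "params")
  thr <- if (!is.null(pr)) pr$quasi_extinction else 1
  tot <- trajectory$total
  ntail <- max(1L, ceiling(tail_fraction * length(tot)))
  longrun <- mean(utils::tail(tot, ntail))
  era <- tot < thr
  eradicated <- any(era)
  if (eradicated) longrun <- 0
  tibble::tibble(
    min_density = min(tot),
    longrun_density = longrun,
    suppression_pct = 100 * (1 - longrun / baseline),
    eradicated = eradicated,
    t_eradication = if (eradicated) trajectory$generation[which(era)[1]]
                    else NA_integer_
  )
}

# internal: fast scenario run on raw vectors; returns the per-cell metrics
# used by phase_scan (release into WT equilibrium at generation 0)
scan_cell <- function(pr, horizon, infiltration_threshold = 0.9) {
  q0 <- wt_equilibrium(pr)
  q <- stats::setNames(numeric(6), queen_classes())
  q["q_ww_w"] <- q0
  q["q_ii_w"] <- pr$release_density
  z <- 1
  t_spread <- NA_integer_; t_erad <- NA_integer_
  min_tot <- sum(q)
  for (t in seq_len(horizon)) {
    st <- step_q(q, z, pr)
    q <- st$q; z <- st$z
    tot <- sum(q)
    min_tot <- min(min_tot, tot)
    if (is.na(t_spread) && tot > 0 &&
        (tot - q[[1]] - q[[2]]) / tot >= infiltration_threshold) {
      t_spread <- t
    }
    if (is.na(t_erad) && tot < pr$quasi_extinction) t_erad <- t
    if (!is.na(t_erad) && !is.na(t_spread)) break
    if (!is.na(t_erad) && tot == 0) break
  }
  final <- sum(q)
  list(t_spread = t_spread, t_erad = t_erad, min_density = min_tot,
       final_density = final)
}

#' Phase scan over homing rate and drone sterility
#'
#' Runs the release-into-equilibrium scenario for every `(h, p)` grid cell
#' and classifies the outcome: did the drive spread through more than
#' `infiltration_threshold` of the queens, was the population eradicated
#' (total below the quasi-extinction threshold), and how much long-run
#' suppression was achieved relative to the wild-type equilibrium.
#'
#' @param params A [drive_params()]; `h` and `p` are overridden cell by
#'   cell, everything else (including `release_density`) is shared.
#' @param h,p Strictly increasing grid vectors within `[0, 1]`.
#' @param horizon Generations per cell; eradication classification wants
#'   `>= 100` (deterministic eradication can take about a century).
#' @param infiltration_threshold Spread criterion on the carrier-queen
#'   fraction. Default 0.9.
#' @return A tibble of class `drive_scan`, one row per grid cell:
#'   `h`, `p`, `spread`, `t_spread`, `eradicated`, `t_eradication`,
#'   `min_density`, `final_density`, `suppression_pct`.
#' @export
phase_scan <- function(params = drive_params(), h = seq(0, 1, by = 0.01),
                       p = seq(0, 1, by = 0.01), horizon = 200L,
                       infiltration_threshold = 0.9) {
  stopifnot(all(h >= 0 & h <= 1), all(p >= 0 & p <= 1),
            !is.unsorted(h, strictly = TRUE),
            !is.unsorted(p, strictly = TRUE), horizon >= 1)
  baseline <- wt_equilibrium(params)
  grid <- tidyr::expand_grid(h = h, p = p)
  cells <- purrr::pmap(grid, function(h, p) {
    pr <- params; pr$h <- h; pr$p <- p
    scan_cell(pr, horizon, infiltration_threshold)
  })
  res <- dplyr::bind_rows(lapply(cells, tibble::as_tibble))
  longrun <- ifelse(is.na(res$t_erad), res$final_density, 0)
  out <- tibble::tibble(
    h = grid$h, p = grid$p,
    spread = !is.na(res$t_spread), t_spread = res$t_spread,
    eradicated = !is.na(res$t_erad), t_eradication = res$t_erad,
    min_density = res$min_density, final_density = res$final_density,
    suppression_pct = 100 * (1 - longrun / baseline)
  )
  structure(out, class = c("drive_scan", class(tibble::tibble())),
            params = params, horizon = horizon, baseline = baseline,
            infiltration_threshold = infiltration_threshold)
}

#' @export
print.drive_scan <- function(x, ...) {
  cat(sprintf("<drive_scan> %d cells | horizon %d generations\n",
              nrow(x), attr(x, "horizon")))
  NextMethod()
}

#' Threshold summary of a phase scan
#'
#' @param x A `drive_scan`.
#' @param ... Unused.
#' @return One-row tibble: the smallest eradication-capable sterility
#'   `p_min_eradication` (at the highest scanned `h`), the smallest
#'   spreading homing rate `h_min_spread` within the eradication-capable
#'   sterility band, and the grid sizes.
#' @export
glance.drive_scan <- function(x, ...) {
  hmax <- max(x$h)
  top <- x[x$h == hmax & x$eradicated, ]
  p_min <- if (nrow(top) > 0) min(top$p) else NA_real_
  band <- x[x$eradicated, ]
  h_min <- if (nrow(band) > 0) min(band$h[band$p == min(band$p)]) else NA_real_
  tibble::tibble(
    p_min_eradication = p_min,
    h_min_spread = h_min,
    n_h = length(unique(x$h)), n_p = length(unique(x$p)),
    horizon = attr(x, "horizon")
  )
}
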