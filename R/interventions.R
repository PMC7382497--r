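#' Timed management events
#'
#' An intervention schedule is an ordered set of release and cull events
#' applied to a simulation. Build one from [release_event()] and
#' [cull_event()] rows. Repeating events (`every`) are unrolled by
#' [expand_schedule()]; within a generation culls are applied before
#' releases, so queens released "immediately following" a cull are not
#' poisoned by it.
#'
#' @param ... Event tibbles from [release_event()] / [cull_event()], or a
#'   single tibble with columns `kind`, `at`, `every`, `magnitude`,
#'   `class`.
#' @return A tibble of class `intervention_schedule`.
#' @examples
#' intervention_schedule(
#'   cull_event(at = 0, fraction = 0.95, every = 10),
#'   release_event(at = 0, density = 100, every = 10)
#' )
#' @export
intervention_schedule <- function(...) {
  evs <- list(...)
  if (length(evs) == 0) {
    out <- tibble::tibble(kind = character(), at = integer(),
                          every = integer(), magnitude = double(),
                          class = character())
  } else {
    out <- dplyr::bind_rows(evs)
  }
  req <- c("kind", "at", "every", "magnitude", "class")
  if (!all(req %in% names(out))) {
    stop("schedule events need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(!out$kind %in% c("release", "cull"))) {
    stop("event kind must be 'release' or 'cull'", call. = FALSE)
  }
  if (any(out$at < 0)) stop("event generations must be >= 0", call. = FALSE)
  if (any(out$magnitude < 0)) stop("magnitudes must be >= 0", call. = FALSE)
  bad_cull <- out$kind == "cull" & out$magnitude > 1
  if (any(bad_cull)) stop("cull kill fraction must be in [0, 1]", call. = FALSE)
  class(out) <- c("intervention_schedule", class(out))
  out
}

#' @rdname intervention_schedule
#' @param at Generation of the (first) occurrence, `>= 0`.
#' @param density Queens per km^2 added by the release.
#' @param class Queen class receiving released queens. The default
#'   `q_ii_w` — homozygous carriers already fertilised by wild-type drones
#'   — is the only class through which a complete-sterility construct can
#'   persist (with `p = 1`, carrier-mated queens raise no workers).
#' @param every Repeat period in generations (`NA` = one-off).
#' @export
release_event <- function(at = 0, density = 100, class = "q_ii_w",
                          every = NA) {
  tibble::tibble(kind = "release", at = as.integer(at),
                 every = as.integer(every), magnitude = density,
                 class = class)
}

#' @rdname intervention_schedule
#' @param fraction Kill fraction in `[0, 1]` applied to every queen class.
#' @export
cull_event <- function(at = 0, fraction = 0.95, every = NA) {
  tibble::tibble(kind = "cull", at = as.integer(at),
                 every = as.integer(every), magnitude = fraction,
                 class = NA_character_)
}

#' Unroll a schedule to explicit per-generation events
#'
#' Repeating events are expanded to every occurrence up to `horizon`
#' (inclusive). Events are ordered by generation, with culls before
#' releases within the same generation.
#'
#' @param schedule An [intervention_schedule()] (or `NULL`).
#' @param horizon Last generation to include, `>= 0`.
#' @return Tibble with columns `generation`, `kind`, `magnitude`, `class`.
#' @export
expand_schedule <- function(schedule, horizon) {
  stopifnot(horizon >= 0)
  empty <- tibble::tibble(generation = integer(), kind = character(),
                          magnitude = double(), class = character())
  if (is.null(schedule) || nrow(schedule) == 0) return(empty)
  rows <- purrr::pmap(schedule, function(kind, at, every, magnitude, class) {
    gens <- if (is.na(every)) at else seq(at, horizon, by = every)
    gens <- gens[gens <= horizon]
    tibble::tibble(generation = as.integer(gens), kind = kind,
                   magnitude = magnitude, class = class)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$generation,
                 factor(.data$kind, levels = c("cull", "release")))
}

#' Release carrier queens into a census
#'
#' Adds `density` queens per km^2 to one queen class; released queens join
#' the summer census directly (they are introduced queens, not gynes
#' competing for nest sites, so the establishment factor `g` does not
#' apply to them).
#'
#' @param state A [population_state()].
#' @param density Queens per km^2, `>= 0`.
#' @param class Target queen class (see [queen_classes()]).
#' @return The updated `population_state`.
#' @export
apply_release <- function(state, density, class = "q_ii_w") {
  stopifnot(density >= 0)
  if (!class %in% queen_classes()) {
    stop("unknown release class: ", class, call. = FALSE)
  }
  state[[class]] <- state[[class]] + density
  state
}

#' Cull a fixed fraction of all queens and nests
#'
#' Multiplies every queen class by `1 - kill_fraction` (e.g. toxic baiting
#' killing 95% of queens and nests). `z` and the generation index are
#' unchanged.
#'
#' @param state A [population_state()].
#' @param kill_fraction Kill fraction in `[0, 1]`.
#' @return The updated `population_state`.
#' @export
apply_cull <- function(state, kill_fraction) {
  if (!is.finite(kill_fraction) || kill_fraction < 0 || kill_fraction > 1) {
    stop("kill_fraction must be in [0, 1]", call. = FALSE)
  }
  for (cl in queen_classes()) state[[cl]] <- state[[cl]] * (1 - kill_fraction)
  state
}
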