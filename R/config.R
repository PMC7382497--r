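#' Run configuration
#'
#' A validated description of a complete run: parameters, initial state,
#' engine, horizon, schedule and optional analysis block. Configs come
#' from [run_config()] directly, from a YAML/JSON file via
#' [load_run_config()], or from a figure preset via [drive_preset()].
#'
#' @param params A [drive_params()] or a named list of parameter
#'   overrides (unknown keys rejected).
#' @param initial `"wt-equilibrium"` (default) or a named list of queen
#'   class densities (plus optional `z`).
#' @param engine `"deterministic"` or `"stochastic"`.
#' @param generations Simulation horizon in years. Default 50.
#' @param replicates Stochastic replicates. Default 1.
#' @param seed Base seed for the stochastic engine (optional).
#' @param schedule An [intervention_schedule()], a list of event maps
#'   (`kind`, `at`, `magnitude`, optional `every`, `class`), or `NULL`.
#' @param analysis Optional analysis block instead of a plain simulation:
#'   `list(type = "phase_scan", h = ..., p = ..., horizon = ...)` or
#'   `list(type = "forced_scan", fractions = ..., m = ..., b = ...)`.
#' @param preset Optional preset name the config was derived from.
#' @return A list of class `run_config`.
#' @export
run_config <- function(params = drive_params(), initial = "wt-equilibrium",
                       engine = c("deterministic", "stochastic"),
                       generations = 50L, replicates = 1L, seed = NULL,
                       schedule = NULL, analysis = NULL, preset = NULL) {
  engine <- match.arg(engine)
  params <- as_drive_params(params)
  if (!(identical(initial, "wt-equilibrium") || is.list(initial))) {
    stop("initial must be \"wt-equilibrium\" or a named list of densities",
         call. = FALSE)
  }
  if (is.list(initial)) {
    bad <- setdiff(names(initial), c(queen_classes(), "z"))
    if (length(bad) > 0) {
      stop("unknown initial-state key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  stopifnot(generations >= 1, replicates >= 1)
  schedule <- as_schedule(schedule)
  if (!is.null(analysis)) {
    if (!is.list(analysis) || is.null(analysis$type) ||
        !analysis$type %in% c("phase_scan", "forced_scan")) {
      stop("analysis$type must be 'phase_scan' or 'forced_scan'",
           call. = FALSE)
    }
  }
  structure(list(params = params, initial = initial, engine = engine,
                 generations = as.integer(generations),
                 replicates = as.integer(replicates), seed = seed,
                 schedule = schedule, analysis = analysis, preset = preset),
            class = "run_config")
}

# accept schedule given as list-of-maps (from YAML/JSON)
as_schedule <- function(x) {
  if (is.null(x) || inherits(x, "intervention_schedule")) return(x)
  if (!is.list(x)) stop("schedule must be a list of events", call. = FALSE)
  rows <- lapply(x, function(ev) {
    if (is.null(ev$kind)) stop("schedule event missing 'kind'", call. = FALSE)
    bad <- setdiff(names(ev), c("kind", "at", "every", "magnitude", "class"))
    if (length(bad) > 0) {
      stop("unknown schedule key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    at <- ev$at %||% 0
    every <- ev$every %||% NA
    if (ev$kind == "release") {
      release_event(at = at, density = ev$magnitude %||% 100,
                    class = ev$class %||% "q_ii_w", every = every)
    } else if (ev$kind == "cull") {
      cull_event(at = at, fraction = ev$magnitude %||% 0.95, every = every)
    } else {
      stop("event kind must be 'release' or 'cull'", call. = FALSE)
    }
  })
  do.call(intervention_schedule, rows)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>",
      if (!is.null(x$preset)) paste0("(preset ", x$preset, ")"), "\n")
  print(x$params)
  cat(sprintf("  engine: %s | generations: %d | replicates: %d\n",
              x$engine, x$generations, x$replicates))
  if (!is.null(x$schedule) && nrow(x$schedule) > 0) {
    cat("  schedule:\n"); print(tibble::as_tibble(x$schedule))
  }
  if (!is.null(x$analysis)) cat("  analysis:", x$analysis$type, "\n")
  invisible(x)
}

#' Load a run configuration from YAML or JSON
#'
#' Missing keys take the model defaults; unknown keys are rejected with
#' the offending name; out-of-range parameters fail parameter validation.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known <- c("params", "initial", "engine", "generations", "replicates",
             "seed", "schedule", "analysis", "preset")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(args$params)) args$params <- as_drive_params(args$params)
  do.call(run_config, args)
}

#' Figure-panel scenario presets
#'
#' Ready-made configurations for the headline scenarios: single releases
#' of 100 carrier queens per km^2 under different homing/sterility
#' combinations (`fig2a`-`fig2g`), forced carrier-fraction suppression
#' curves (`fig3a`, `fig3b`), the homing x sterility phase scan
#' (`fig4a`), drive release combined with culling (`fig4b`), and
#' ten-yearly management programmes (`fig5a`-`fig5e`). The `fig4b` preset
#' encodes the combined programme (release every 10 years, each
#' immediately after a 95% cull); drop events from its schedule for the
#' one-off / no-cull variants. `fig5d` and `fig5e` contrast a low
#' (`h = 0.8`) and a high (`h = 0.95`) homing rate under the combined
#' programme.
#'
#' @param name One of `fig2a`-`fig2g`, `fig3a`, `fig3b`, `fig4a`,
#'   `fig4b`, `fig5a`-`fig5e`.
#' @return A [run_config()].
#' @examples
#' drive_preset("fig2b")  # fitness-neutral drive sweep
#' @export
drive_preset <- function(name) {
  one_release <- intervention_schedule(release_event(at = 0, density = 100))
  ten_yearly <- function(cull = TRUE, release = TRUE) {
    evs <- list()
    if (cull) evs <- c(evs, list(cull_event(at = 0, fraction = 0.95,
                                            every = 10)))
    if (release) evs <- c(evs, list(release_event(at = 0, density = 100,
                                                  every = 10)))
    do.call(intervention_schedule, evs)
  }
  sim <- function(h, p, gens = 50L, schedule = one_release) {
    run_config(params = drive_params(h = h, p = p), generations = gens,
               schedule = schedule, preset = name)
  }
  switch(name,
    # one-off introductions (Fig 2): 100 carrier queens/km^2 at time 0
    fig2a = sim(h = 0,   p = 1),    # plain sterility gene, no drive
    fig2b = sim(h = 1,   p = 0),    # fitness-neutral drive
    fig2c = sim(h = 1,   p = 1),    # complete-sterility drive
    fig2d = sim(h = 1,   p = 0.3),  # 70% of carrier matings succeed
    fig2e = sim(h = 0.8, p = 0),    # imperfect homing, neutral
    fig2f = sim(h = 0.8, p = 1),    # imperfect homing, complete sterility
    fig2g = sim(h = 0.8, p = 0.3),  # imperfect homing, partial sterility
    # forced carrier-fraction suppression curves
    fig3a = run_config(params = drive_params(h = 1, p = 1),
                       analysis = list(type = "forced_scan",
                                       fractions = seq(0, 1, by = 0.02),
                                       m = c(1, 2, 2.5, 5, 10)),
                       preset = name),
    fig3b = run_config(params = drive_params(h = 1, p = 1),
                       analysis = list(type = "forced_scan",
                                       fractions = seq(0, 1, by = 0.02),
                                       b = c(0, 0.5, 1, 2)),
                       preset = name),
    # homing x sterility phase behaviour
    fig4a = run_config(params = drive_params(),
                       analysis = list(type = "phase_scan",
                                       h = seq(0.8, 1, by = 0.01),
                                       p = seq(0, 1, by = 0.01),
                                       horizon = 500L),
                       preset = name),
    fig4b = sim(h = 0.8, p = 1, gens = 100L, schedule = ten_yearly()),
    # ten-yearly management programmes
    fig5a = sim(h = 1, p = 1, gens = 100L,
                schedule = ten_yearly(release = FALSE)),
    fig5b = sim(h = 1, p = 1, gens = 100L,
                schedule = ten_yearly(cull = FALSE)),
    fig5c = sim(h = 1, p = 1, gens = 100L, schedule = ten_yearly()),
    fig5d = sim(h = 0.8, p = 1, gens = 100L, schedule = ten_yearly()),
    fig5e = sim(h = 0.95, p = 1, gens = 100L, schedule = ten_yearly()),
    stop("unknown preset: ", name, call. = FALSE)
  )
}

#' List the available presets
#' @return Character vector of preset names.
#' @export
preset_names <- function() {
  c(paste0("fig2", letters[1:7]), "fig3a", "fig3b", "fig4a", "fig4b",
    paste0("fig5", letters[1:5]))
}

#' Execute a run configuration
#'
#' Dispatches to the deterministic or stochastic engine, or to the
#' configured analysis (phase scan / forced-fraction scan).
#'
#' @param config A [run_config()].
#' @return A `drive_trajectory`, `drive_ensemble`, `drive_scan`, or (for
#'   a forced scan) a tibble of equilibrium densities per carrier
#'   fraction and parameter value.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pr <- config$params
  if (!is.null(config$analysis)) {
    an <- config$analysis
    if (an$type == "phase_scan") {
      return(phase_scan(pr, h = an$h %||% seq(0, 1, by = 0.01),
                        p = an$p %||% seq(0, 1, by = 0.01),
                        horizon = an$horizon %||% 200L))
    }
    return(forced_scan(pr, fractions = an$fractions %||% seq(0, 1, 0.02),
                       m = an$m, b = an$b))
  }
  init_dens <- if (identical(config$initial, "wt-equilibrium")) {
    stats::setNames(as.list(c(wt_equilibrium(pr), numeric(5))),
                    queen_classes())
  } else {
    config$initial
  }
  if (config$engine == "deterministic") {
    initial <- do.call(population_state, init_dens)
    simulate_drive(initial, pr, generations = config$generations,
                   schedule = config$schedule)
  } else {
    cnt <- init_dens
    for (cl in queen_classes()) {
      if (!is.null(cnt[[cl]])) cnt[[cl]] <- round(cnt[[cl]])
    }
    initial <- do.call(integer_state, cnt)
    stochastic_simulate(initial, pr, generations = config$generations,
                        replicates = config$replicates,
                        schedule = config$schedule, seed = config$seed)
  }
}

#' Forced carrier-fraction suppression curves
#'
#' Evaluates [forced_fraction_equilibrium()] on a grid of pinned carrier
#' fractions, optionally sweeping the polyandry `m` or the sperm-load
#' exponent `b`.
#'
#' @param params Base [drive_params()] (typically `p = 1`).
#' @param fractions Carrier-fraction grid in `[0, 1]`.
#' @param m,b Optional vectors of polyandry / sperm-load values to sweep;
#'   `NULL` keeps the base value.
#' @return Tibble with columns `carrier_fraction`, `m`, `b`,
#'   `equilibrium_density`, `suppression_pct`.
#' @export
forced_scan <- function(params = drive_params(h = 1, p = 1),
                        fractions = seq(0, 1, by = 0.02),
                        m = NULL, b = NULL) {
  grid <- tidyr::expand_grid(carrier_fraction = fractions,
                             m = m %||% params$m, b = b %||% params$b)
  base <- wt_equilibrium(params)
  dens <- purrr::pmap_dbl(grid, function(carrier_fraction, m, b) {
    pr <- params; pr$m <- m; pr$b <- b
    forced_fraction_equilibrium(carrier_fraction, pr)
  })
  dplyr::mutate(grid, equilibrium_density = dens,
                suppression_pct = 100 * (1 - dens / base))
}
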