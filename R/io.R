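#' Write a trajectory (or scan) to CSV with a JSON metadata sidecar
#'
#' The CSV holds one row per generation (or grid cell) in a fixed column
#' order; full numeric precision is kept so a round trip reproduces the
#' values exactly. A `<path>.meta.json` sidecar records the parameters,
#' schedule, seed and package version, making the run reproducible from
#' the two files alone.
#'
#' @param trajectory A `drive_trajectory`.
#' @param path Output CSV path.
#' @param seed Seed to record in the sidecar (optional).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, seed = NULL) {
  readr::write_csv(tibble::as_tibble(trajectory), path)
  write_sidecar(path, params = attr(trajectory, "params"),
                schedule = attr(trajectory, "schedule"), seed = seed)
  invisible(path)
}

#' @rdname write_trajectory
#' @param scan A `drive_scan` from [phase_scan()].
#' @export
write_scan <- function(scan, path, seed = NULL) {
  readr::write_csv(tibble::as_tibble(scan), path)
  write_sidecar(path, params = attr(scan, "params"), schedule = NULL,
                seed = seed, horizon = attr(scan, "horizon"))
  invisible(path)
}

write_sidecar <- function(path, params, schedule, seed, ...) {
  meta <- list(
    package = "waspdrive",
    version = as.character(utils::packageVersion("waspdrive")),
    params = unclass(params),
    schedule = if (!is.null(schedule)) {
      as.list(tibble::as_tibble(schedule))
    },
    seed = seed,
    ...
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Restores the tibble and, when the metadata sidecar is present, the
#' parameter attributes.
#'
#' @param path CSV path.
#' @return A `drive_trajectory` (plain tibble if no sidecar is found).
#' @export
read_trajectory <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = "NA")
  df$generation <- as.integer(df$generation)
  if ("events" %in% names(df)) df$events <- as.character(df$events)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) return(df)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pars <- as_drive_params(as.list(meta$params))
  sched <- if (!is.null(meta$schedule) && length(meta$schedule) > 0) {
    cols <- lapply(meta$schedule, function(x) if (is.null(x)) NA else x)
    intervention_schedule(tibble::as_tibble(cols))
  }
  new_drive_trajectory(df, pars, sched)
}
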