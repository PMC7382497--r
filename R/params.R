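#' Model parameters for the wasp gene-drive recursion
#'
#' Bundles every scalar parameter of the annual queen recursion together with
#' the run controls shared by the deterministic and stochastic engines.
#' Defaults are the *Vespula vulgaris* values used throughout: queens mate
#' with 2.5 drones on average, 2% of gynes survive winter, nest-site
#' competition caps the summer nest density near 1,350 per square kilometre,
#' and each nest can produce 560 gynes.
#'
#' @param h Homing (conversion) probability: chance that a heterozygous
#'   offspring is converted to a homozygous drive carrier. In `[0, 1]`.
#' @param p Drone sterility: probability that a mating with a carrier drone
#'   transfers *no* viable sperm. `p = 1` is complete drone sterility. In
#'   `[0, 1]`.
#' @param c Relative mating competitiveness of carrier drones, in `[0, 1]`.
#' @param m Mean number of matings per gyne (polyandry), a real exponent
#'   `> 0`. Default 2.5.
#' @param s Overwinter gyne survival proportion, in `(0, 1]`. Default 0.02.
#' @param n Nest-site competition factor, nests per km^2. Default 1500.
#' @param lambda Potential gynes produced per nest. Default 560.
#' @param b Sperm-load fecundity exponent: per-nest gyne output is scaled by
#'   `Z^b` where `Z` is the viable-sperm load of the current queen
#'   generation. `b = 0` (default) switches the effect off.
#' @param release_density Carrier queens introduced per release event,
#'   queens per km^2. Default 100.
#' @param quasi_extinction Density below which the deterministic population
#'   is declared eradicated (the model never reaches exactly zero). Default
#'   1 nest per km^2.
#'
#' @return An object of class `drive_params`: a validated named list.
#' @examples
#' drive_params()                 # wild-type defaults, no drive
#' drive_params(h = 1, p = 0.3)   # homing drive, 30% sterile matings
#' @export
drive_params <- function(h = 0, p = 0, c = 1, m = 2.5, s = 0.02, n = 1500,
                         lambda = 560, b = 0, release_density = 100,
                         quasi_extinction = 1) {
  pr <- list(h = h, p = p, c = c, m = m, s = s, n = n, lambda = lambda,
             b = b, release_density = release_density,
             quasi_extinction = quasi_extinction)
  validate_drive_params(pr)
  structure(pr, class = "drive_params")
}

validate_drive_params <- function(pr) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk <- function(ok, what) {
    if (!ok) stop("invalid parameter: ", what, call. = FALSE)
  }
  for (nm in names(pr)) chk(num1(pr[[nm]]), paste(nm, "must be a finite number"))
  chk(pr$h >= 0 && pr$h <= 1, "h must be in [0, 1]")
  chk(pr$p >= 0 && pr$p <= 1, "p must be in [0, 1]")
  chk(pr$c >= 0 && pr$c <= 1, "c must be in [0, 1]")
  chk(pr$m > 0, "m must be > 0")
  chk(pr$s > 0 && pr$s <= 1, "s must be in (0, 1]")
  chk(pr$n > 0, "n must be > 0")
  chk(pr$lambda > 0, "lambda must be > 0")
  chk(pr$b >= 0, "b must be >= 0")
  chk(pr$release_density >= 0, "release_density must be >= 0")
  chk(pr$quasi_extinction >= 0, "quasi_extinction must be >= 0")
  invisible(pr)
}

#' @export
print.drive_params <- function(x, ...) {
  cat("<drive_params>\n")
  cat(sprintf("  drive:      h = %g, p = %g, c = %g\n", x$h, x$p, x$c))
  cat(sprintf("  life cycle: m = %g, s = %g, n = %g, lambda = %g, b = %g\n",
              x$m, x$s, x$n, x$lambda, x$b))
  cat(sprintf("  controls:   release_density = %g, quasi_extinction = %g\n",
              x$release_density, x$quasi_extinction))
  invisible(x)
}

#' Coerce a list (e.g. from a config file) to drive_params
#' @noRd
as_drive_params <- function(x) {
  if (inherits(x, "drive_params")) return(x)
  stopifnot(is.list(x))
  known <- names(formals(drive_params))
  bad <- setdiff(names(x), known)
  if (length(bad) > 0) {
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(drive_params, x)
}
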