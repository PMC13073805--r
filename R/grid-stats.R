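#' Unit constants for potential rescaling
#'
#' The mesh Ewald potential is reported in units of kT/e at 300 K. The
#' conventional rescale factor used throughout this package is 0.0258 V per
#' kT300/e; the exact CODATA value kB*300K/e = 0.0258520 V is exposed
#' alongside (the two differ by about 0.2%).
#'
#' @return A list with `kt300_over_e_volts` (conventional factor, default
#'   used by [rescale_to_volts()]) and `kt300_over_e_volts_exact`.
#' @examples
#' unit_constants()
#' @export
unit_constants <- function() {
  list(
    kt300_over_e_volts = 0.0258,
    kt300_over_e_volts_exact = 1.380649e-23 * 300 / 1.602176634e-19
  )
}

#' Per-point time mean and standard deviation over a sequence of grids
#'
#' Accumulates the temporal mean `<phi(r_i)>` and the population standard
#' deviation `sigma(r_i) = sqrt(<phi^2> - <phi>^2)` (divide-by-N variance)
#' over frames.
#'
#' @param grids A list of [potential_grid()] objects sharing one spec and
#'   units.
#' @param allow_center_drift If `TRUE`, grids must agree in counts, box and
#'   units but may differ in center (the per-frame re-centered convention);
#'   the first grid's spec is kept and the maximum center deviation recorded
#'   as attribute `center_drift`.
#' @return A [grid_stats()].
#' @export
accumulate_stats <- function(grids, allow_center_drift = FALSE) {
  if (length(grids) == 0) abort("accumulate_stats needs at least one grid")
  if (!all(vapply(grids, inherits, logical(1), "potential_grid"))) {
    abort("accumulate_stats expects potential_grid objects")
  }
  ref <- grids[[1]]
  drift <- 0
  for (g in grids[-1]) {
    if (g$units != ref$units) abort("grids have mismatching units")
    if (!spec_equal(g$spec, ref$spec, ignore_center = allow_center_drift)) {
      abort("grids have mismatching grid specs")
    }
    if (allow_center_drift) {
      drift <- max(drift, max(abs(g$spec$center - ref$spec$center)))
    }
  }
  n <- length(grids)
  m <- Reduce(`+`, lapply(grids, `[[`, "values")) / n
  # <phi^2> - <phi>^2, evaluated in its shifted (two-pass) form <(phi - <phi>)^2>
  # to avoid catastrophic cancellation when fluctuations are tiny
  v <- Reduce(`+`, lapply(grids, function(g) (g$values - m)^2)) / n
  out <- grid_stats(ref$spec, m, sqrt(v), n_frames = n, units = ref$units)
  if (allow_center_drift) attr(out, "center_drift") <- drift
  out
}

#' Rescale a grid from kT300/e to volts
#'
#' Multiplies values (or mean and sigma) by the kT300/e-to-volt factor and
#' flags the object as volt-denominated. Re-applying to a grid already in
#' volts is an error, guarding against double rescaling.
#'
#' @param g A [potential_grid()] or [grid_stats()] in `kT300_per_e` units.
#' @param factor Volts per kT300/e; the conventional 0.0258 by default (pass
#'   `unit_constants()$kt300_over_e_volts_exact` for the exact constant).
#' @return The same type of object, in volts.
#' @export
rescale_to_volts <- function(g, factor = unit_constants()$kt300_over_e_volts) {
  if (inherits(g, "potential_grid")) {
    if (g$units == "volt") abort("grid is already in volts")
    potential_grid(g$spec, g$values * factor, units = "volt")
  } else if (inherits(g, "grid_stats")) {
    if (g$units == "volt") abort("grid stats are already in volts")
    grid_stats(g$spec, g$mean * factor, g$sigma * factor,
               n_frames = g$n_frames, units = "volt")
  } else {
    abort("rescale_to_volts expects a potential_grid or grid_stats")
  }
}
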