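#' Reference characterization of the HSP60/HSP10 upper cavity
#'
#' The reported long-range electrostatic characterization of the human
#' mitochondrial chaperonin's upper folding chamber, as obtained from a
#' 200-ns all-atom MD study: the maximal inscribed cavity ellipsoid, the
#' linear and quadratic polynomial models of the time-averaged reciprocal
#' space potential fitted on 15,160 control points, their coefficients of
#' determination, the control-point counts before and after the 0.5 V sigma
#' filter, and the mapping grid geometry. These values serve as the default
#' worked example, as inputs for consistency checks, and as the basis of the
#' synthetic surrogate control-point set
#' ([make_reference_control_points()]) — the underlying trajectory is not
#' redistributable.
#'
#' @return A list with elements `ellipsoid`, `model_linear`,
#'   `model_quadratic` (both [polynomial_model()]s with the published
#'   coefficients), `r_squared` (named vector for orders 1 and 2),
#'   `n_inside`, `n_kept`, `sigma_max`, `grid` (a [grid_spec()] of the
#'   120^3 mapping grid), and `n_frames`.
#' @examples
#' ref <- hsp60_cavity()
#' field_of(ref$model_linear)
#' @export
hsp60_cavity <- function() {
  e <- ellipsoid(
    center = c(188.875, 188.341, 235.258),
    radii = c(28.11, 28.16, 22.32)
  )
  linear <- polynomial_model(
    c(-4.0521e1, 5.4487e-3, -1.0490e-2, 1.6188e-1),
    order = 1, validity_region = e
  )
  quadratic <- polynomial_model(
    c(-5.8778e1, 4.0177e-1, 5.2559e-2, -4.9239e-2,
      -7.7542e-4, 2.3151e-4, -6.2183e-4, -6.0596e-4, 5.1593e-4, 4.8898e-4),
    order = 2, validity_region = e
  )
  list(
    ellipsoid = e,
    model_linear = linear,
    model_quadratic = quadratic,
    r_squared = c(order1 = 0.9740, order2 = 0.9892),
    n_inside = 16551L,
    n_kept = 15160L,
    sigma_max = 0.5,
    grid = grid_spec(c(120, 120, 120), box = c(171.36, 171.26, 263.09),
                     center = e$center),
    n_frames = 1000L
  )
}

#' Percentage of in-ellipsoid points removed by the sigma filter
#'
#' @param n_inside Grid points inside the ellipsoid.
#' @param n_kept Points surviving the sigma threshold.
#' @return Percent removed, `100 * (n_inside - n_kept) / n_inside`.
#' @export
percent_removed <- function(n_inside, n_kept) {
  if (n_inside < 1 || n_kept > n_inside) abort("need 0 < n_kept <= n_inside")
  100 * (n_inside - n_kept) / n_inside
}
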