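#' Axis-aligned ellipsoid
#'
#' @param center Length-3 numeric center (Å).
#' @param radii Length-3 positive semi-axes (a, b, c) in Å.
#' @return An `ellipsoid` object.
#' @examples
#' ellipsoid(c(188.875, 188.341, 235.258), c(28.11, 28.16, 22.32))
#' @export
ellipsoid <- function(center, radii) {
  center <- as.numeric(center)
  radii <- as.numeric(radii)
  if (length(center) != 3 || length(radii) != 3) abort("center and radii must be length 3")
  if (any(!is.finite(center)) || any(!is.finite(radii))) abort("non-finite ellipsoid parameters")
  if (any(radii <= 0)) abort("ellipsoid radii must be > 0")
  structure(list(center = center, radii = radii), class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf(
    "<ellipsoid> center (%.3f, %.3f, %.3f) Å, radii (%.3f, %.3f, %.3f) Å\n",
    x$center[1], x$center[2], x$center[3], x$radii[1], x$radii[2], x$radii[3]
  ))
  invisible(x)
}

ellipsoid_volume <- function(e) 4 / 3 * pi * prod(e$radii)

#' Quadratic form of points with respect to an ellipsoid
#'
#' `(x-cx)^2/a^2 + (y-cy)^2/b^2 + (z-cz)^2/c^2`; equals 1 on the surface.
#'
#' @param p Point(s): length-3 vector, matrix, or data frame with x, y, z.
#' @param e An [ellipsoid()].
#' @return Numeric vector of quadratic-form values.
#' @export
ellipsoid_quad_form <- function(p, e) {
  m <- point_matrix(p)
  rel <- sweep(m, 2, e$center)
  rel <- sweep(rel, 2, e$radii, `/`)
  rowSums(rel^2)
}

#' Strict point-in-ellipsoid membership
#'
#' A point is inside when its quadratic form is strictly below 1; surface
#' points are outside.
#'
#' @inheritParams ellipsoid_quad_form
#' @return Logical vector.
#' @export
point_in_ellipsoid <- function(p, e) {
  ellipsoid_quad_form(p, e) < 1
}

point_matrix <- function(p) {
  if (is.data.frame(p)) {
    m <- cbind(p$x, p$y, p$z)
  } else if (is.matrix(p)) {
    m <- p[, 1:3, drop = FALSE]
  } else {
    m <- matrix(as.numeric(p), ncol = 3)
  }
  storage.mode(m) <- "double"
  m
}

#' Scan settings for cavity ellipsoid inscription
#'
#' @param dz_scan Axial offsets (Å) to scan for the ellipsoid center,
#'   relative to the half-assembly centroid.
#' @param shrink_margin Margin (Å) subtracted from each semi-axis after the
#'   maximal ellipsoid is found, in original (unscaled) coordinates.
#' @param inversion_radius_factor The inversion sphere radius as a multiple
#'   of the largest scaled atom distance.
#' @param half Which cavity to inscribe: the half above (`"upper"`) or below
#'   (`"lower"`) the xy plane through the assembly centroid.
#' @return An `inscription_spec` list.
#' @export
inscription_spec <- function(dz_scan = seq(-6, 6, by = 1), shrink_margin = 1,
                             inversion_radius_factor = 10,
                             half = c("upper", "lower")) {
  if (length(dz_scan) < 1) abort("dz_scan must be non-empty")
  if (shrink_margin < 0) abort("shrink_margin must be >= 0")
  if (inversion_radius_factor <= 1) abort("inversion_radius_factor must be > 1")
  structure(
    list(dz_scan = as.numeric(dz_scan), shrink_margin = shrink_margin,
         inversion_radius_factor = inversion_radius_factor,
         half = match.arg(half)),
    class = "inscription_spec"
  )
}

#' Largest axis-aligned ellipsoid inscribed in a barrel cavity
#'
#' Implements the geometric-inversion inscription, per scanned axial offset
#' dz: (a) center all atoms at the assembly centroid; (b) keep the requested
#' half (z >= 0 for upper); (c) re-center the half at its centroid and shift
#' the candidate center by dz along z; (d) rescale coordinates by the half's
#' bounding-box dimensions (A, B, C); (e) invert the scaled cloud inside out,
#' `r'' = (R/|r'| - 1) r'` with R a large multiple of the maximal scaled
#' distance; (f) the enclosing-sphere radius of the inverted cloud maps back
#' to the scaled inscribed radius `rho = R - R_enclosing`, giving candidate
#' semi-axes `(A, B, C) * rho`. The offset maximizing the ellipsoid volume
#' wins; the shrink margin is then subtracted from each semi-axis in original
#' Å. Every atom center of the scanned half lies on or outside the pre-shrink
#' ellipsoid and strictly outside the returned one.
#'
#' @param frame A [charge_frame()] (or coordinate matrix).
#' @param spec An [inscription_spec()].
#' @return An [ellipsoid()] in the input coordinate frame, with attributes
#'   `dz_best`, `radii_pre_shrink`, `rho` and `half`.
#' @seealso [brute_force_inscribed()] for the direct-minimization oracle.
#' @export
inscribe_ellipsoid <- function(frame, spec = inscription_spec()) {
  xyz <- if (is.matrix(frame)) frame else frame_coords(frame)
  com <- colMeans(xyz)
  centered <- sweep(xyz, 2, com)
  sel <- if (spec$half == "upper") centered[, 3] >= 0 else centered[, 3] <= 0
  if (!any(sel)) {
    abort(sprintf("no atoms in the %s half of the assembly", spec$half))
  }
  if (all(sel)) {
    abort("all atoms lie on one side of the xy plane through the centroid")
  }
  half <- centered[sel, , drop = FALSE]
  com_half <- colMeans(half)
  dims <- apply(half, 2, function(v) diff(range(v)))
  if (any(dims <= 0)) abort("degenerate (flat) half-assembly; cannot inscribe")

  best <- list(rho = -Inf, dz = NA_real_)
  for (dz in spec$dz_scan) {
    cand_center <- com_half + c(0, 0, dz)
    scaled <- sweep(sweep(half, 2, cand_center), 2, dims, `/`)
    rnorm_ <- sqrt(rowSums(scaled^2))
    if (min(rnorm_) == 0) next  # an atom sits exactly at the candidate center
    big_r <- spec$inversion_radius_factor * max(rnorm_)
    inverted <- scaled * (big_r / rnorm_ - 1)
    r_enclosing <- max(sqrt(rowSums(inverted^2)))
    rho <- big_r - r_enclosing
    if (rho > best$rho) best <- list(rho = rho, dz = dz, center = cand_center)
  }
  if (!is.finite(best$rho) || best$rho <= 0) abort("no inscribable ellipsoid found")
  radii_pre <- dims * best$rho
  radii <- radii_pre - spec$shrink_margin
  if (any(radii <= 0)) {
    abort(sprintf(
      "cavity too small: pre-shrink radii (%.3f, %.3f, %.3f) Å do not survive the %.2f Å margin",
      radii_pre[1], radii_pre[2], radii_pre[3], spec$shrink_margin
    ))
  }
  out <- ellipsoid(center = com + best$center, radii = radii)
  attr(out, "dz_best") <- best$dz
  attr(out, "radii_pre_shrink") <- radii_pre
  attr(out, "rho") <- best$rho
  attr(out, "half") <- spec$half
  out
}

#' Largest inscribed ellipsoid of fixed center and aspect, by direct search
#'
#' Oracle counterpart of [inscribe_ellipsoid()]: with the center and the
#' axis ratios fixed, the largest ellipsoid containing no atom center has
#' semi-axes `aspect * min_a |((r_a - center)/aspect)|`, found by direct
#' minimization over atoms.
#'
#' @param frame A [charge_frame()] or coordinate matrix.
#' @param center Length-3 ellipsoid center (Å).
#' @param aspect Length-3 positive axis ratios.
#' @return An [ellipsoid()].
#' @export
brute_force_inscribed <- function(frame, center, aspect) {
  xyz <- if (is.matrix(frame)) frame else frame_coords(frame)
  if (nrow(xyz) < 1) abort("need at least one atom")
  aspect <- as.numeric(aspect)
  if (any(aspect <= 0)) abort("aspect ratios must be > 0")
  scaled <- sweep(sweep(xyz, 2, as.numeric(center)), 2, aspect, `/`)
  rho <- min(sqrt(rowSums(scaled^2)))
  if (rho <= 0) abort("an atom coincides with the requested center")
  ellipsoid(center = center, radii = aspect * rho)
}
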