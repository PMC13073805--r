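#' Regular periodic grid specification
#'
#' Defines an axis-aligned, node-centered grid of `counts` points spread over
#' an orthorhombic box of side lengths `box`, centered at `center`. The grid
#' origin is the minimum corner, `center - box/2`; point `(i, j, k)`
#' (0-based) sits at `origin + (i*dx, j*dy, k*dz)` with `dx = Lx/nx` etc., so
#' the mesh tiles the periodic cell without duplicating the wrapped face.
#'
#' @param counts Integer vector of length 3 (nx, ny, nz), each >= 1.
#' @param box Numeric length-3 box side lengths in Å.
#' @param center Numeric length-3 box center in Å.
#' @return A `grid_spec` object.
#' @examples
#' grid_spec(c(120, 120, 120), box = c(171.36, 171.26, 263.09))
#' @export
grid_spec <- function(counts, box, center = c(0, 0, 0)) {
  counts <- as.integer(counts)
  if (length(counts) != 3 || any(counts < 1)) abort("counts must be 3 integers >= 1")
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) abort("box lengths must be 3 positive numbers")
  center <- as.numeric(center)
  if (length(center) != 3) abort("center must be length 3")
  structure(
    list(counts = counts, box = box, center = center, spacing = box / counts),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %dx%dx%d over %.2f x %.2f x %.2f Å (spacing %.4f %.4f %.4f)\n",
    x$counts[1], x$counts[2], x$counts[3], x$box[1], x$box[2], x$box[3],
    x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

grid_origin <- function(spec) spec$center - spec$box / 2

#' Grid point coordinates along each axis
#'
#' @param spec A [grid_spec()].
#' @return A list with numeric vectors `x`, `y`, `z` of node coordinates (Å).
#' @export
grid_axes <- function(spec) {
  o <- grid_origin(spec)
  list(
    x = o[1] + (seq_len(spec$counts[1]) - 1) * spec$spacing[1],
    y = o[2] + (seq_len(spec$counts[2]) - 1) * spec$spacing[2],
    z = o[3] + (seq_len(spec$counts[3]) - 1) * spec$spacing[3]
  )
}

#' All grid points as a tibble in canonical order
#'
#' Canonical ordering is z-major: z varies slowest, then y, then x fastest —
#' the same order as the underlying value array's linear layout.
#'
#' @param spec A [grid_spec()].
#' @return Tibble with columns x, y, z.
#' @export
grid_points <- function(spec) {
  ax <- grid_axes(spec)
  as_tibble(expand.grid(x = ax$x, y = ax$y, z = ax$z, KEEP.OUT.ATTRS = FALSE))
}

spec_equal <- function(a, b, ignore_center = FALSE, tol = 1e-9) {
  ok <- identical(a$counts, b$counts) &&
    max(abs(a$box - b$box)) < tol
  if (!ignore_center) ok <- ok && max(abs(a$center - b$center)) < tol
  ok
}

#' Scalar potential on a grid
#'
#' @param spec A [grid_spec()].
#' @param values 3D numeric array of dim `spec$counts` (or a vector of the
#'   right length, filled x-fastest).
#' @param units `"kT300_per_e"` or `"volt"`.
#' @return A `potential_grid` object.
#' @export
potential_grid <- function(spec, values, units = c("kT300_per_e", "volt")) {
  units <- match.arg(units)
  stopifnot(inherits(spec, "grid_spec"))
  if (!is.array(values)) values <- array(values, dim = spec$counts)
  if (!identical(dim(values), as.integer(spec$counts))) {
    abort("value array dimensions do not match grid counts")
  }
  if (!all(is.finite(values))) abort("grid values must be finite")
  structure(list(spec = spec, values = values, units = units),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf(
    "<potential_grid> %dx%dx%d [%s], range [%.4g, %.4g]\n",
    x$spec$counts[1], x$spec$counts[2], x$spec$counts[3], x$units,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Per-point temporal mean and standard deviation of a potential
#'
#' @param spec A [grid_spec()].
#' @param mean,sigma 3D arrays of dim `spec$counts`; `sigma >= 0`.
#' @param n_frames Number of frames averaged.
#' @param units Units shared by mean and sigma.
#' @return A `grid_stats` object.
#' @export
grid_stats <- function(spec, mean, sigma, n_frames,
                       units = c("kT300_per_e", "volt")) {
  units <- match.arg(units)
  stopifnot(inherits(spec, "grid_spec"))
  if (!is.array(mean)) mean <- array(mean, dim = spec$counts)
  if (!is.array(sigma)) sigma <- array(sigma, dim = spec$counts)
  if (!identical(dim(mean), as.integer(spec$counts)) ||
      !identical(dim(sigma), as.integer(spec$counts))) {
    abort("mean/sigma dimensions do not match grid counts")
  }
  if (any(sigma < 0)) abort("sigma must be >= 0 everywhere")
  if (n_frames < 1) abort("n_frames must be >= 1")
  structure(
    list(spec = spec, mean = mean, sigma = sigma,
         n_frames = as.integer(n_frames), units = units),
    class = "grid_stats"
  )
}

#' @export
print.grid_stats <- function(x, ...) {
  cat(sprintf(
    "<grid_stats> %dx%dx%d [%s], N = %d frames; mean in [%.4g, %.4g], sigma in [%.4g, %.4g]\n",
    x$spec$counts[1], x$spec$counts[2], x$spec$counts[3], x$units, x$n_frames,
    min(x$mean), max(x$mean), min(x$sigma), max(x$sigma)
  ))
  invisible(x)
}
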