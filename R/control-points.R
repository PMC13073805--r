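#' Select low-variance grid points inside the cavity ellipsoid
#'
#' Applies the two control-point restrictions to a volt-denominated
#' [grid_stats()]: a grid point is kept when it lies strictly inside the
#' ellipsoid (quadratic form < 1) and its temporal standard deviation is
#' strictly below `sigma_max`. Points come out in canonical grid order
#' (z slowest, then y, then x fastest).
#'
#' @param stats A [grid_stats()] in volts.
#' @param e The cavity [ellipsoid()].
#' @param sigma_max Fluctuation threshold in volts (default 0.5 V).
#' @return A `control_points` tibble with columns x, y, z (Å), `phi` and
#'   `sigma` (V), and provenance attributes `ellipsoid`, `sigma_max`,
#'   `n_inside` (points inside the ellipsoid) and `n_kept`.
#' @export
select_control_points <- function(stats, e, sigma_max = 0.5) {
  stopifnot(inherits(stats, "grid_stats"), inherits(e, "ellipsoid"))
  if (stats$units != "volt") {
    abort("grid stats must be rescaled to volts before control-point selection")
  }
  if (!is.numeric(sigma_max) || sigma_max <= 0) abort("sigma_max must be > 0")
  pts <- grid_points(stats$spec)
  inside <- point_in_ellipsoid(pts, e)
  n_inside <- sum(inside)
  if (n_inside == 0) abort("no grid point lies inside the ellipsoid")
  phi <- as.vector(stats$mean)[inside]
  sig <- as.vector(stats$sigma)[inside]
  keep <- sig < sigma_max
  out <- dplyr::bind_cols(pts[inside, ][keep, ], tibble(phi = phi[keep], sigma = sig[keep]))
  attr(out, "ellipsoid") <- e
  attr(out, "sigma_max") <- sigma_max
  attr(out, "n_inside") <- as.integer(n_inside)
  attr(out, "n_kept") <- as.integer(sum(keep))
  class(out) <- c("control_points", class(out))
  out
}

#' @export
print.control_points <- function(x, ...) {
  ni <- attr(x, "n_inside")
  if (!is.null(ni)) {
    cat(sprintf(
      "<control_points> %d kept of %d inside the ellipsoid (%.1f%% removed, sigma_max %.3g V)\n",
      attr(x, "n_kept"), ni, 100 * (ni - attr(x, "n_kept")) / ni, attr(x, "sigma_max")
    ))
  }
  NextMethod()
}

#' Distribution of sigma over the in-ellipsoid grid points
#'
#' Summarizes the temporal standard deviation of the potential over all grid
#' points inside the cavity ellipsoid (before any threshold filtering):
#' a density-normalized histogram, the empirical CDF, and the CDF of a
#' normal distribution with the sample mean and standard deviation.
#'
#' @param stats A [grid_stats()].
#' @param e The cavity [ellipsoid()].
#' @param bins Number of histogram bins (>= 1).
#' @return A `sigma_distribution` object: a list with `bins` (tibble of
#'   lower/upper/mid/density), `sigma` (the raw values), `ecdf`, `normal`
#'   (mean/sd), and `n`.
#' @seealso [exceed_fraction()], [autoplot.sigma_distribution()]
#' @export
sigma_distribution <- function(stats, e, bins = 40) {
  stopifnot(inherits(stats, "grid_stats"), inherits(e, "ellipsoid"))
  if (bins < 1) abort("bins must be >= 1")
  pts <- grid_points(stats$spec)
  sig <- as.vector(stats$sigma)[point_in_ellipsoid(pts, e)]
  if (length(sig) < 2) abort("need at least 2 in-ellipsoid points")
  rng <- range(sig)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]), 1) * 1e-6
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(sig, breaks = breaks, plot = FALSE)
  structure(
    list(
      bins = tibble(
        lower = head(h$breaks, -1), upper = tail(h$breaks, -1),
        mid = h$mids, density = h$density
      ),
      sigma = sig,
      ecdf = ecdf(sig),
      normal = list(mean = mean(sig), sd = sd(sig)),
      n = length(sig)
    ),
    class = "sigma_distribution"
  )
}

#' @export
print.sigma_distribution <- function(x, ...) {
  cat(sprintf(
    "<sigma_distribution> n = %d, mean %.4g, sd %.4g (%d bins)\n",
    x$n, x$normal$mean, x$normal$sd, nrow(x$bins)
  ))
  invisible(x)
}

#' Fraction of in-ellipsoid points whose sigma exceeds a threshold
#'
#' @param dist A [sigma_distribution()].
#' @param threshold Threshold in the same units as sigma (V).
#' @return Fraction in `[0, 1]`.
#' @export
exceed_fraction <- function(dist, threshold) {
  stopifnot(inherits(dist, "sigma_distribution"))
  mean(dist$sigma > threshold)
}
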