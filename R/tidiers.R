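#' Tidy a fitted polynomial potential
#'
#' One row per term: the monomial label, its exponent triple, the estimated
#' coefficient (V/Å^degree) and, for fitted models, the standard error from
#' the least-squares coefficient covariance.
#'
#' @param x A `potential_fit` or `polynomial_model`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `a`, `b`, `c`, `estimate` and
#'   (when available) `std.error`.
#' @export
tidy.polynomial_model <- function(x, ...) {
  out <- x$terms
  if (!is.null(x$std_error)) out$std.error <- x$std_error
  out
}

#' @export
tidy.potential_fit <- tidy.polynomial_model

#' One-row fit summary
#'
#' @param x A `potential_fit`.
#' @param ... Unused.
#' @return A tibble with `order`, `r.squared`, `sigma` (residual standard
#'   deviation, V), `nobs` and `df.residual`.
#' @export
glance.potential_fit <- function(x, ...) {
  tibble(
    order = x$order,
    r.squared = x$r_squared,
    sigma = sqrt(x$sigma2),
    nobs = x$n,
    df.residual = x$n - nrow(x$terms)
  )
}

#' Augment control points with fitted potentials and residuals
#'
#' @param x A `potential_fit`.
#' @param data The control points the model was fitted to (or any point set
#'   with x, y, z and optionally `phi`).
#' @param ... Unused.
#' @return `data` with `.fitted` and (when `phi` is present) `.resid`.
#' @export
augment.potential_fit <- function(x, data, ...) {
  out <- as_tibble(data)
  out$.fitted <- evaluate_potential(x, data, warn_outside = FALSE)
  if (!is.null(out[["phi"]])) out$.resid <- out$phi - out$.fitted
  out
}

#' @export
predict.polynomial_model <- function(object, newdata, ...) {
  evaluate_potential(object, newdata, warn_outside = FALSE)
}
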