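monomial_exponents <- function(order) {
  if (order == 1) {
    list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else if (order == 2) {
    # constant, linear, then x^2, xy, xz, y^2, yz, z^2
    list(
      c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
      c(2, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 2, 0), c(0, 1, 1), c(0, 0, 2)
    )
  } else {
    abort("order must be 1 or 2")
  }
}

term_label <- function(expts) {
  vapply(expts, function(e) {
    if (all(e == 0)) return("1")
    paste0(c("x", "y", "z")[e > 0][rep(seq_len(sum(e > 0)), e[e > 0])], collapse = "*")
  }, character(1))
}

#' Polynomial potential model
#'
#' A polynomial in the raw Cartesian coordinates,
#' `phi(r) = sum_a C_a x^a1 y^a2 z^a3`, with coefficients in
#' V / Å^(a1+a2+a3). Order 1 carries 4 terms (constant plus gradient),
#' order 2 the full 10-term quadratic.
#'
#' @param coefficients Numeric vector of coefficients in canonical term
#'   order (see [build_design()]): length 4 (order 1) or 10 (order 2).
#' @param order Polynomial order, 1 or 2.
#' @param validity_region Optional [ellipsoid()] within which the model is
#'   meant to be evaluated.
#' @return A `polynomial_model` object.
#' @export
polynomial_model <- function(coefficients, order = NULL, validity_region = NULL) {
  if (is.null(order)) order <- if (length(coefficients) == 4) 1 else 2
  expts <- monomial_exponents(order)
  if (length(coefficients) != length(expts)) {
    abort(sprintf("order-%d model needs %d coefficients, got %d",
                  order, length(expts), length(coefficients)))
  }
  terms <- tibble(
    term = term_label(expts),
    a = vapply(expts, `[`, numeric(1), 1),
    b = vapply(expts, `[`, numeric(1), 2),
    c = vapply(expts, `[`, numeric(1), 3),
    estimate = as.numeric(coefficients)
  )
  structure(
    list(terms = terms, order = as.integer(order),
         validity_region = validity_region),
    class = "polynomial_model"
  )
}

#' @export
print.polynomial_model <- function(x, ...) {
  cat(sprintf("<polynomial_model> order %d\n", x$order))
  print(as.data.frame(x$terms[, c("term", "estimate")]), row.names = FALSE)
  if (!is.null(x$r_squared)) cat(sprintf("R^2 = %.4f on %d points\n", x$r_squared, x$n))
  invisible(x)
}

#' Assemble the least-squares design system for a polynomial potential
#'
#' Builds the N x (M+1) design matrix of monomial values (first column all
#' ones, then the coordinates raw in Å — no centering) and the observation
#' vector of potentials.
#'
#' @param points A data frame with columns x, y, z and `phi` (the
#'   control-point set).
#' @param order Polynomial order, 1 or 2.
#' @return A `design_system`: list with `M` (design matrix), `F`
#'   (observations), `exponents`, `order`.
#' @export
build_design <- function(points, order = 1) {
  expts <- monomial_exponents(order)
  n <- nrow(points)
  if (n < length(expts)) {
    abort(sprintf("need at least %d points for an order-%d fit, got %d",
                  length(expts), order, n))
  }
  m <- design_matrix(points, expts)
  structure(
    list(M = m, F = points$phi, exponents = expts, order = order),
    class = "design_system"
  )
}

design_matrix <- function(points, expts) {
  x <- points$x; y <- points$y; z <- points$z
  m <- vapply(expts, function(e) x^e[1] * y^e[2] * z^e[3], numeric(length(x)))
  m <- matrix(m, nrow = length(x))
  colnames(m) <- term_label(expts)
  m
}

#' Fit a polynomial potential to control points by least squares
#'
#' Solves the minimum-residual problem `M A = F` through an orthogonal (QR)
#' decomposition of the design; rank decisions use the singular value
#' spectrum with a relative cutoff of 1e-10, and a rank-deficient design
#' raises an error naming the unresolvable term. Coordinates enter the
#' design raw (global Å); with `center = TRUE` they are first shifted to the
#' centroid for conditioning and the coefficients mapped back, leaving
#' predictions identical.
#'
#' @param points A control-point tibble (columns x, y, z, phi).
#' @param order Polynomial order, 1 or 2.
#' @param center Use centered coordinates internally (default `FALSE`).
#' @return A `potential_fit` (inherits `polynomial_model`) carrying
#'   `r_squared`, residual variance, coefficient covariance and standard
#'   errors, and the selection ellipsoid (when the input has one) as its
#'   validity region.
#' @export
fit_potential <- function(points, order = 1, center = FALSE) {
  ds <- build_design(points, order)
  m <- ds$M
  f <- ds$F
  shift <- c(0, 0, 0)
  if (center) {
    shift <- c(mean(points$x), mean(points$y), mean(points$z))
    shifted <- dplyr::mutate(as_tibble(points),
                             x = .data$x - shift[1],
                             y = .data$y - shift[2],
                             z = .data$z - shift[3])
    m <- design_matrix(shifted, ds$exponents)
  }
  check_design_rank(m)
  qr_m <- qr(m)
  coef <- qr.coef(qr_m, f)
  if (center) coef <- uncenter_coefficients(coef, ds$exponents, shift)
  model <- polynomial_model(coef, order = order,
                            validity_region = attr(points, "ellipsoid"))
  fitted <- as.numeric(ds$M %*% model$terms$estimate)
  res <- f - fitted
  p <- ncol(ds$M)
  n <- length(f)
  sigma2 <- sum(res^2) / max(n - p, 1)
  xtx_inv <- chol2inv(qr.R(qr(ds$M)))
  model$r_squared <- r_squared_values(f, fitted)
  model$sigma2 <- sigma2
  model$cov <- sigma2 * xtx_inv
  model$std_error <- sqrt(diag(model$cov))
  model$n <- n
  model$residuals <- res
  class(model) <- c("potential_fit", class(model))
  model
}

check_design_rank <- function(m) {
  d <- svd(m, nu = 0)$d
  cutoff <- 1e-10 * max(d)
  if (any(d < cutoff)) {
    sv <- svd(m)
    null_vec <- sv$v[, which(sv$d < cutoff)[1]]
    worst <- colnames(m)[which.max(abs(null_vec))]
    abort(sprintf(
      "design matrix is rank deficient: points do not resolve the '%s' term (e.g. all points coplanar)",
      worst
    ))
  }
  invisible(TRUE)
}

# map coefficients of a polynomial in (r - s) back to raw-coordinate form
uncenter_coefficients <- function(coef, expts, shift) {
  out <- numeric(length(expts))
  key <- vapply(expts, paste, character(1), collapse = ",")
  for (i in seq_along(expts)) {
    e <- expts[[i]]
    # expand (x-sx)^e1 (y-sy)^e2 (z-sz)^e3 term by term
    for (ax in 0:e[1]) for (ay in 0:e[2]) for (az in 0:e[3]) {
      w <- choose(e[1], ax) * choose(e[2], ay) * choose(e[3], az) *
        (-shift[1])^(e[1] - ax) * (-shift[2])^(e[2] - ay) * (-shift[3])^(e[3] - az)
      j <- match(paste(c(ax, ay, az), collapse = ","), key)
      out[j] <- out[j] + coef[i] * w
    }
  }
  out
}

r_squared_values <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("R^2 is undefined: all observed values are equal")
  1 - sum((y - fitted)^2) / ss_tot
}

#' Coefficient of determination of a model on a point set
#'
#' `R^2 = 1 - sum((Y_i - f_i)^2) / sum((Y_i - Ybar)^2)`.
#'
#' @param model A `polynomial_model`.
#' @param points Data frame with x, y, z and observed `phi`.
#' @return R-squared (dimensionless, <= 1).
#' @export
r_squared <- function(model, points) {
  fitted <- evaluate_potential(model, points)
  r_squared_values(points$phi, fitted)
}

#' Evaluate a polynomial potential
#'
#' @param model A `polynomial_model`.
#' @param p Point(s): length-3 vector, matrix, or data frame with x, y, z.
#' @param warn_outside Warn when points fall outside the model's validity
#'   ellipsoid (default `TRUE`).
#' @return Numeric vector of potentials (V).
#' @export
evaluate_potential <- function(model, p, warn_outside = TRUE) {
  m <- point_matrix(p)
  if (warn_outside && !is.null(model$validity_region)) {
    outside <- ellipsoid_quad_form(m, model$validity_region) >= 1
    if (any(outside)) {
      warn(sprintf("%d point(s) outside the model's validity ellipsoid", sum(outside)))
    }
  }
  acc <- numeric(nrow(m))
  for (i in seq_len(nrow(model$terms))) {
    t <- model$terms[i, ]
    acc <- acc + t$estimate * m[, 1]^t$a * m[, 2]^t$b * m[, 3]^t$c
  }
  acc
}

#' Electric field of a polynomial potential
#'
#' The negative analytic gradient. An order-1 model yields a constant field,
#' independent of position; an order-2 model must be evaluated at points.
#'
#' @param model A `polynomial_model`.
#' @param p Evaluation point(s); optional for order-1 models.
#' @return A `field_vector` tibble with columns `ex`, `ey`, `ez` (V/Å), plus
#'   the evaluation coordinates for position-dependent fields. Attribute
#'   `constant` flags position independence.
#' @export
field_of <- function(model, p = NULL) {
  constant <- all(model$terms$a + model$terms$b + model$terms$c <= 1)
  if (is.null(p)) {
    if (!constant) abort("a non-constant (order-2) field needs evaluation points `p`")
    p <- matrix(0, nrow = 1, ncol = 3)
    keep_xyz <- FALSE
  } else {
    keep_xyz <- !constant
  }
  m <- point_matrix(p)
  comp <- matrix(0, nrow = nrow(m), ncol = 3)
  for (i in seq_len(nrow(model$terms))) {
    t <- model$terms[i, ]
    e <- c(t$a, t$b, t$c)
    for (d in 1:3) {
      if (e[d] == 0) next
      ed <- e
      ed[d] <- ed[d] - 1
      comp[, d] <- comp[, d] -
        t$estimate * e[d] * m[, 1]^ed[1] * m[, 2]^ed[2] * m[, 3]^ed[3]
    }
  }
  out <- tibble(ex = comp[, 1], ey = comp[, 2], ez = comp[, 3])
  if (keep_xyz) out <- dplyr::bind_cols(tibble(x = m[, 1], y = m[, 2], z = m[, 3]), out)
  class(out) <- c("field_vector", class(out))
  attr(out, "constant") <- constant
  out
}

#' Per-point relative field components
#'
#' Evaluates the field at each control point and reports each component
#' relative to the total magnitude: `|Ex|/|E|`, `|Ey|/|E|` and `-Ez/|E|`
#' (the sign convention that makes a downward axial field positive), plus
#' the magnitude itself. Rows with zero-magnitude field are flagged rather
#' than dropped.
#'
#' @param model A `polynomial_model`.
#' @param points Control points (data frame with x, y, z).
#' @return A tibble in the input point order with columns `rel_ex`,
#'   `rel_ey`, `rel_ez_down` (= -Ez/|E|), `magnitude`, `ez_sign` and
#'   `degenerate`; attribute `summary` holds `min_rel_ez_down`,
#'   `max_rel_ex`, `max_rel_ey` and `ez_sign_constant`.
#' @export
relative_components <- function(model, points) {
  f <- field_of(model, p = points)
  if (isTRUE(attr(f, "constant")) && nrow(f) == 1) {
    f <- f[rep(1, nrow(points)), ]
  }
  mag <- sqrt(f$ex^2 + f$ey^2 + f$ez^2)
  degenerate <- mag == 0
  safe <- ifelse(degenerate, NA_real_, mag)
  out <- tibble(
    rel_ex = abs(f$ex) / safe,
    rel_ey = abs(f$ey) / safe,
    rel_ez_down = -f$ez / safe,
    magnitude = mag,
    ez_sign = sign(f$ez),
    degenerate = degenerate
  )
  ok <- !degenerate
  attr(out, "summary") <- if (any(ok)) {
    list(
      min_rel_ez_down = min(out$rel_ez_down[ok]),
      max_rel_ex = max(out$rel_ex[ok]),
      max_rel_ey = max(out$rel_ey[ok]),
      ez_sign_constant = length(unique(out$ez_sign[ok])) == 1
    )
  } else {
    list(min_rel_ez_down = NA_real_, max_rel_ex = NA_real_,
         max_rel_ey = NA_real_, ez_sign_constant = NA)
  }
  out
}

#' Format a constant field as an MD-engine electric-field keyword
#'
#' Converts the chosen component from V/Å to V/nm (factor 10) and prints it
#' to 4 significant figures in the 4-field constant-field convention, e.g.
#' `electric-field-z = -1.619 0 0 0`.
#'
#' @param field A constant `field_vector` (from an order-1 model), or an
#'   order-1 `polynomial_model`.
#' @param axis Which component to export: "x", "y" or "z".
#' @return The keyword line as a string.
#' @export
export_field_keyword <- function(field, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  if (inherits(field, "polynomial_model")) field <- field_of(field)
  if (!isTRUE(attr(field, "constant"))) {
    abort("only a constant (order-1) field can be exported as an engine keyword")
  }
  comp <- field[[paste0("e", axis)]][1]
  v_nm <- 10 * comp  # V/Å -> V/nm
  sprintf("electric-field-%s = %s 0 0 0", axis,
          format(signif(v_nm, 4), scientific = FALSE, trim = TRUE))
}
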