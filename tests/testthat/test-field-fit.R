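random_points <- function(n = 200, seed = 1, half_width = 20,
                          center = c(0, 0, 0)) {
  withr::with_seed(seed, tibble::tibble(
    x = runif(n, center[1] - half_width, center[1] + half_width),
    y = runif(n, center[2] - half_width, center[2] + half_width),
    z = runif(n, center[3] - half_width, center[3] + half_width)
  ))
}

test_that("design rows are the expected monomials in canonical order", {
  pt <- tibble::tibble(x = 1, y = 2, z = 3, phi = 0)
  d1 <- build_design(dplyr::bind_rows(pt, pt, pt, pt), order = 1)
  expect_equal(unname(d1$M[1, ]), c(1, 1, 2, 3))
  expect_true(all(d1$M[, 1] == 1))
  pts10 <- dplyr::bind_rows(replicate(10, pt, simplify = FALSE))
  d2 <- build_design(pts10, order = 2)
  expect_equal(unname(d2$M[1, ]), c(1, 1, 2, 3, 1, 2, 3, 4, 6, 9))
  expect_equal(dim(d2$M), c(10, 10))
  expect_error(build_design(pt, order = 2), "at least 10")
})

test_that("a noiseless planted linear potential is recovered exactly", {
  truth <- c(2, -0.05, 0.1, 0.16)
  pts <- random_points(200, seed = 2)
  pts$phi <- truth[1] + truth[2] * pts$x + truth[3] * pts$y + truth[4] * pts$z
  fit <- fit_potential(pts, order = 1)
  expect_lt(max(abs(fit$terms$estimate - truth)), 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # quadratic fit of linear truth is also exact with zero quadratic terms
  fit2 <- fit_potential(pts, order = 2)
  expect_lt(max(abs(fit2$terms$estimate[5:10])), 1e-10)
})

test_that("solution and residuals match an independent normal-equations solve", {
  pts <- random_points(300, seed = 5)
  truth2 <- polynomial_model(
    c(1, 0.02, -0.01, 0.05, 4e-4, -2e-4, 1e-4, 3e-4, -1e-4, 5e-4), order = 2)
  pts$phi <- evaluate_potential(truth2, pts)
  fit1 <- fit_potential(pts, order = 1)  # deliberate underfit
  expect_lt(fit1$r_squared, 1)
  m <- build_design(pts, order = 1)$M
  beta_ne <- solve(crossprod(m), crossprod(m, pts$phi))
  expect_lt(max(abs(fit1$terms$estimate - beta_ne)) / max(abs(beta_ne)), 1e-8)
  res_ne <- pts$phi - as.numeric(m %*% beta_ne)
  expect_lt(max(abs(fit1$residuals - res_ne)), 1e-8)
  # and the full quadratic fit is exact again
  fit2 <- fit_potential(pts, order = 2)
  expect_lt(max(abs(fit2$terms$estimate - truth2$terms$estimate)), 1e-9)
})

test_that("R^2 follows its defining formula and rejects degenerate data", {
  pts <- random_points(50, seed = 7)
  pts$phi <- withr::with_seed(8, rnorm(50))
  m <- polynomial_model(c(mean(pts$phi), 0, 0, 0), order = 1)
  expect_equal(r_squared(m, pts), 0, tolerance = 1e-12)
  fit <- fit_potential(pts, order = 1)
  y <- pts$phi
  f <- evaluate_potential(fit, pts, warn_outside = FALSE)
  expect_equal(fit$r_squared, 1 - sum((y - f)^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  pts$phi <- 3
  expect_error(fit_potential(pts, order = 1), "undefined")
})

test_that("rank-deficient designs fail loudly, naming the missing direction", {
  pts <- random_points(80, seed = 9)
  pts$z <- 5  # coplanar
  pts$phi <- withr::with_seed(10, rnorm(80))
  expect_error(fit_potential(pts, order = 1), "rank deficient")
})

test_that("centered fitting reproduces raw-coordinate predictions", {
  pts <- random_points(150, seed = 11, center = c(190, 190, 235))
  truth2 <- polynomial_model(
    c(-58, 0.4, 0.05, -0.05, -8e-4, 2e-4, -6e-4, -6e-4, 5e-4, 5e-4), order = 2)
  pts$phi <- evaluate_potential(truth2, pts) + withr::with_seed(12, rnorm(150, sd = 0.2))
  raw <- fit_potential(pts, order = 2)
  cen <- fit_potential(pts, order = 2, center = TRUE)
  expect_lt(max(abs(predict(raw, pts) - predict(cen, pts))), 1e-7)
})

test_that("an additive potential constant shifts only the intercept", {
  pts <- random_points(120, seed = 13)
  pts$phi <- 1 - 0.02 * pts$x + 0.05 * pts$y - 0.1 * pts$z +
    withr::with_seed(14, rnorm(120, sd = 0.1))
  f1 <- fit_potential(pts, order = 1)
  pts2 <- pts
  pts2$phi <- pts$phi + 7.5
  f2 <- fit_potential(pts2, order = 1)
  expect_equal(f2$terms$estimate[1] - f1$terms$estimate[1], 7.5, tolerance = 1e-10)
  expect_lt(max(abs(f2$terms$estimate[2:4] - f1$terms$estimate[2:4])), 1e-10)
})

test_that("the quadratic fit never has lower R^2 than the linear fit", {
  for (seed in 1:3) {
    pts <- random_points(100, seed = seed)
    pts$phi <- 0.1 * pts$z + withr::with_seed(seed + 50, rnorm(100, sd = 0.5))
    expect_gte(fit_potential(pts, order = 2)$r_squared,
               fit_potential(pts, order = 1)$r_squared - 1e-12)
  }
})

test_that("noisy planted gradients are recovered within 3 standard errors", {
  truth <- hsp60_cavity()$model_linear$terms$estimate
  e <- hsp60_cavity()$ellipsoid
  pts <- random_points(12000, seed = 15, half_width = 20, center = e$center)
  pts$phi <- truth[1] + truth[2] * pts$x + truth[3] * pts$y + truth[4] * pts$z +
    withr::with_seed(16, rnorm(12000, sd = 0.5))
  fit <- fit_potential(pts, order = 1)
  zscores <- (fit$terms$estimate - truth) / fit$std_error
  expect_lt(max(abs(zscores)), 3)
})

test_that("potential evaluation reproduces the published-model arithmetic", {
  ref <- hsp60_cavity()
  ctr <- ref$ellipsoid$center
  expected <- -4.0521e1 + 5.4487e-3 * ctr[1] - 1.0490e-2 * ctr[2] +
    1.6188e-1 * ctr[3]
  expect_equal(evaluate_potential(ref$model_linear, ctr), expected,
               tolerance = 1e-12)
  m0 <- polynomial_model(c(4.2, 0, 0, 0), order = 1)
  expect_equal(evaluate_potential(m0, c(100, -50, 3)), 4.2)
  diff_model <- polynomial_model(ref$model_linear$terms$estimate -
                                   ref$model_linear$terms$estimate, order = 1)
  expect_equal(evaluate_potential(diff_model, ctr), 0)
  expect_warning(evaluate_potential(ref$model_linear, ctr + c(100, 0, 0)),
                 "outside")
})

test_that("the field is the negative gradient, constant for order 1", {
  ref <- hsp60_cavity()
  f <- field_of(ref$model_linear)
  expect_true(attr(f, "constant"))
  expect_equal(c(f$ex, f$ey, f$ez), c(-5.4487e-3, 1.0490e-2, -1.6188e-1))
  f0 <- field_of(polynomial_model(c(3, 0, 0, 0), order = 1))
  expect_equal(c(f0$ex, f0$ey, f0$ez), c(0, 0, 0))
  # order-2 field matches a central-difference gradient at random points
  q <- ref$model_quadratic
  pts <- random_points(50, seed = 17, half_width = 15, center = ref$ellipsoid$center)
  fv <- field_of(q, pts)
  h <- 1e-4
  for (d in 1:3) {
    up <- pts
    dn <- pts
    up[[d]] <- up[[d]] + h
    dn[[d]] <- dn[[d]] - h
    num <- -(evaluate_potential(q, up, warn_outside = FALSE) -
               evaluate_potential(q, dn, warn_outside = FALSE)) / (2 * h)
    expect_lt(max(abs(num - fv[[c("ex", "ey", "ez")[d]]])), 1e-6)
  }
})

test_that("relative components report axial dominance correctly", {
  down <- polynomial_model(c(0, 0, 0, 1), order = 1)  # E = (0, 0, -1)
  pts <- random_points(20, seed = 18)
  rc <- relative_components(down, pts)
  expect_true(all(rc$rel_ex == 0))
  expect_true(all(rc$rel_ez_down == 1))
  expect_true(attr(rc, "summary")$ez_sign_constant)

  iso <- polynomial_model(c(0, -1 / sqrt(3), -1 / sqrt(3), -1 / sqrt(3)), order = 1)
  rc2 <- relative_components(iso, pts)
  expect_equal(rc2$rel_ex, rep(1 / sqrt(3), 20))
  expect_equal(rc2$rel_ey, rep(1 / sqrt(3), 20))
  expect_equal(rc2$rel_ez_down, rep(-1 / sqrt(3), 20))

  flat <- polynomial_model(c(5, 0, 0, 0), order = 1)
  rc3 <- relative_components(flat, pts)
  expect_true(all(rc3$degenerate))
})

test_that("field keyword export converts V/Å to V/nm at 4 significant figures", {
  lin <- hsp60_cavity()$model_linear
  expect_equal(export_field_keyword(lin, axis = "z"),
               "electric-field-z = -1.619 0 0 0")
  zero <- polynomial_model(c(1, 0, 0, 0), order = 1)
  expect_equal(export_field_keyword(zero, axis = "z"),
               "electric-field-z = 0 0 0 0")
  tenth <- polynomial_model(c(0, 0, 0, 0.1), order = 1)
  expect_equal(export_field_keyword(tenth, axis = "z"),
               "electric-field-z = -1 0 0 0")
  expect_equal(export_field_keyword(lin, axis = "x"),
               "electric-field-x = -0.05449 0 0 0")
  expect_error(export_field_keyword(hsp60_cavity()$model_quadratic), "constant")
})

test_that("tidy/glance/augment expose the fit in broom shape", {
  pts <- random_points(60, seed = 19)
  pts$phi <- 1 + 0.1 * pts$z + withr::with_seed(20, rnorm(60, sd = 0.2))
  fit <- fit_potential(pts, order = 1)
  td <- tidy(fit)
  expect_equal(td$term, c("1", "x", "y", "z"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 60)
  expect_equal(gl$order, 1)
  expect_equal(gl$r.squared, fit$r_squared)
  au <- augment(fit, pts)
  expect_equal(au$.resid, pts$phi - au$.fitted)
})
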