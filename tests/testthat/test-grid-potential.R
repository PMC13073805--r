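test_that("superposition undoes an exact rigid motion", {
  ref <- withr::with_seed(10, matrix(rnorm(45, sd = 6), ncol = 3))
  moved <- rigid_motion(ref, angle = pi / 2, axis = "z", shift = c(5, 0, 0))
  traj <- as_trajectory(list(frame_from_matrix(ref), frame_from_matrix(moved)))
  aligned <- align_to_reference(traj, 1)
  rmsd <- attr(aligned, "rmsd")
  expect_equal(rmsd[1], 0)  # reference onto itself
  expect_lt(rmsd[2], 1e-8)
  expect_lt(max(abs(frame_coords(aligned[[2]]) - ref)), 1e-8)
})

test_that("post-fit RMSD of a jittered rigid copy matches the bio3d oracle", {
  skip_if_not_installed("bio3d")
  ref <- withr::with_seed(11, matrix(rnorm(90, sd = 8), ncol = 3))
  jitter <- withr::with_seed(12, matrix(rnorm(90, sd = 0.2), ncol = 3))
  moved <- rigid_motion(ref + jitter, angle = 1.1, axis = "x", shift = c(-3, 7, 2))
  traj <- as_trajectory(list(frame_from_matrix(ref), frame_from_matrix(moved)))
  aligned <- align_to_reference(traj, 1)
  fitted <- suppressWarnings(bio3d::fit.xyz(
    fixed = as.vector(t(ref)),
    mobile = matrix(as.vector(t(moved)), nrow = 1)
  ))
  oracle_rmsd <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - ref)^2)))
  expect_equal(attr(aligned, "rmsd")[2], oracle_rmsd, tolerance = 1e-8)
  # jitter of sd s in 3 coordinates gives post-fit rmsd near s*sqrt(3) per atom
  expect_lt(abs(attr(aligned, "rmsd")[2] - 0.2 * sqrt(3)), 0.1)
})

test_that("superposition rejects degenerate references", {
  line <- cbind(1:10, 2 * (1:10), -(1:10))
  traj <- as_trajectory(list(frame_from_matrix(line), frame_from_matrix(line)))
  expect_error(align_to_reference(traj, 1), "collinear")
  two <- matrix(rnorm(6), ncol = 3)
  traj2 <- as_trajectory(list(frame_from_matrix(two), frame_from_matrix(two)))
  expect_error(align_to_reference(traj2, 1), "3 atoms")
})

test_that("mesh potential is zero for zero charges and linear in charges", {
  spec <- cube_spec(32, 60)
  f0 <- random_frame(6, seed = 1)
  f0$charge <- 0
  expect_true(all(pme_reciprocal_grid(f0, spec)$values == 0))

  f <- random_frame(6, seed = 1)
  g1 <- pme_reciprocal_grid(f, spec)
  f2 <- f
  f2$charge <- 2 * f$charge
  g2 <- pme_reciprocal_grid(f2, spec)
  expect_lt(max(abs(g2$values - 2 * g1$values)), 1e-12 * max(abs(g1$values)))
})

test_that("mesh potential agrees with the direct reciprocal k-sum oracle", {
  spec <- cube_spec(32, 60)
  pme <- pme_params(ewald_beta = 0.25, spline_order = 4, kmax = 20)
  f <- random_frame(8, seed = 42)
  g <- pme_reciprocal_grid(f, spec, pme)
  ax <- grid_axes(spec)
  idx <- withr::with_seed(5, cbind(sample(32, 20, TRUE), sample(32, 20, TRUE),
                                   sample(32, 20, TRUE)))
  pts <- cbind(ax$x[idx[, 1]], ax$y[idx[, 2]], ax$z[idx[, 3]])
  # the B-spline interpolation error concentrates at charge sites; compare
  # away from them, per-point where the potential is appreciable
  xyz <- frame_coords(f)
  dist_min <- apply(pts, 1, function(p) min(sqrt(colSums((t(xyz) - p)^2))))
  away <- dist_min > 4
  expect_gt(sum(away), 10)
  direct <- ewald_reciprocal_direct(f, spec, pme, pts[away, ])
  mesh <- g$values[idx[away, , drop = FALSE]]
  expect_lt(max(abs(mesh - direct)) / max(abs(direct)), 1e-3)
})

test_that("a symmetric charge pair gives an antisymmetric potential in z", {
  l <- 64
  n <- 32
  spec <- grid_spec(c(n, n, n), box = c(l, l, l), center = c(l / 2, l / 2, l / 2))
  z0 <- 8
  f <- charge_frame(tibble::tibble(
    x = c(l / 2, l / 2), y = c(l / 2, l / 2),
    z = c(l / 2 + z0, l / 2 - z0), charge = c(1, -1)
  ))
  g <- pme_reciprocal_grid(f, spec)
  # grid node z index k maps to z = k*dz; antisymmetry pairs k with n-k (mod n)
  flipped <- g$values[, , c(1, n:2)]
  # the z = box/2 plane maps onto itself; values there must vanish
  expect_lt(max(abs(g$values + flipped)), 1e-6 * max(abs(g$values)))
})

test_that("potential is covariant under joint translation of charges and grid", {
  f <- random_frame(5, seed = 9)
  spec <- cube_spec(32, 60)
  g1 <- pme_reciprocal_grid(f, spec)
  shift <- c(7.3, -4.1, 2.2)
  f2 <- f
  f2$x <- f$x + shift[1]; f2$y <- f$y + shift[2]; f2$z <- f$z + shift[3]
  spec2 <- grid_spec(spec$counts, spec$box, center = spec$center + shift)
  g2 <- pme_reciprocal_grid(f2, spec2)
  expect_lt(max(abs(g2$values - g1$values)), 1e-10 * max(abs(g1$values)))
})

test_that("direct k-sum is linear, converged by kmax 16, and validates input", {
  spec <- cube_spec(32, 60)
  f <- random_frame(4, seed = 1)
  pts <- withr::with_seed(3, matrix(runif(15, 10, 50), ncol = 3))
  f0 <- f; f0$charge <- 0
  expect_equal(ewald_reciprocal_direct(f0, spec, pme_params(), pts), rep(0, 5))
  p1 <- ewald_reciprocal_direct(f, spec, pme_params(kmax = 16), pts)
  f2 <- f; f2$charge <- 2 * f$charge
  expect_equal(ewald_reciprocal_direct(f2, spec, pme_params(kmax = 16), pts), 2 * p1)
  p2 <- ewald_reciprocal_direct(f, spec, pme_params(kmax = 24), pts)
  expect_lt(max(abs(p1 - p2)), 1e-5)
})

test_that("PME validates grid size against the spline order", {
  f <- random_frame(3, seed = 2)
  expect_error(pme_reciprocal_grid(f, grid_spec(c(4, 32, 32), box = c(60, 60, 60))),
               "at least 8")
  expect_error(grid_spec(c(32, 32, 32), box = c(0, 60, 60)), "positive")
})

test_that("accumulated stats match the population mean/sd formulas", {
  spec <- grid_spec(c(8, 8, 8), box = c(8, 8, 8), center = rep(4, 3))
  a <- potential_grid(spec, array(0, dim = c(8, 8, 8)))
  b <- potential_grid(spec, array(2, dim = c(8, 8, 8)))
  st <- accumulate_stats(list(a, b))
  expect_true(all(st$mean == 1))
  expect_true(all(st$sigma == 1))  # <phi^2> - <phi>^2 = 2 - 1
  expect_equal(st$n_frames, 2)

  st2 <- accumulate_stats(list(a, a))
  expect_true(all(st2$sigma == 0))
  expect_equal(st2$mean, a$values)
})

test_that("accumulated stats agree with a two-pass oracle on random inputs", {
  spec <- grid_spec(c(6, 5, 4), box = c(6, 5, 4), center = c(0, 0, 0))
  grids <- withr::with_seed(8, lapply(1:7, function(i) {
    potential_grid(spec, array(rnorm(120, sd = 3), dim = c(6, 5, 4)))
  }))
  st <- accumulate_stats(grids)
  stacked <- sapply(grids, function(g) as.vector(g$values))
  expect_lt(max(abs(as.vector(st$mean) - rowMeans(stacked))), 1e-12)
  two_pass_sd <- apply(stacked, 1, function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(as.vector(st$sigma) - two_pass_sd)), 1e-12)
})

test_that("stats over 1000 noise frames recover the generating moments", {
  spec <- grid_spec(c(8, 8, 8), box = rep(8, 3), center = rep(0, 3))
  vals <- withr::with_seed(21, matrix(rnorm(1000, mean = -3, sd = 0.4), ncol = 1000))
  grids <- lapply(seq_len(1000), function(i) {
    potential_grid(spec, array(vals[1, i], dim = c(8, 8, 8)))
  })
  st <- accumulate_stats(grids)
  expect_lt(abs(st$mean[1, 1, 1] - (-3)), 0.04)
  expect_lt(abs(st$sigma[1, 1, 1] - 0.4), 0.03)
})

test_that("stats accumulation rejects empty input and mismatched specs", {
  expect_error(accumulate_stats(list()), "at least one")
  s1 <- grid_spec(c(8, 8, 8), box = rep(8, 3), center = rep(0, 3))
  s2 <- grid_spec(c(8, 8, 8), box = rep(8, 3), center = c(1, 0, 0))
  a <- potential_grid(s1, array(0, dim = c(8, 8, 8)))
  b <- potential_grid(s2, array(0, dim = c(8, 8, 8)))
  expect_error(accumulate_stats(list(a, b)), "mismatch")
  expect_silent(accumulate_stats(list(a, b), allow_center_drift = TRUE))
})

test_that("volt rescaling multiplies by the conventional factor once", {
  spec <- grid_spec(c(8, 8, 8), box = rep(8, 3), center = rep(0, 3))
  g <- potential_grid(spec, array(1, dim = c(8, 8, 8)))
  v <- rescale_to_volts(g)
  expect_equal(v$values[1], 0.0258)
  expect_equal(v$units, "volt")
  expect_error(rescale_to_volts(v), "already in volts")
  g0 <- potential_grid(spec, array(0, dim = c(8, 8, 8)))
  expect_true(all(rescale_to_volts(g0)$values == 0))
  # exact constant from CODATA values is within 0.2% of the convention
  uc <- unit_constants()
  expect_lt(abs(uc$kt300_over_e_volts_exact - uc$kt300_over_e_volts) /
              uc$kt300_over_e_volts, 0.0025)
  expect_equal(uc$kt300_over_e_volts_exact, 0.02585, tolerance = 1e-3)
})
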