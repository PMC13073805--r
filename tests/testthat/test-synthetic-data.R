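test_that("barrel trajectories are pure functions of the spec and seed", {
  spec <- barrel_spec(n_wall_atoms = 300, n_cap_atoms = 30, n_frames = 3, seed = 21)
  t1 <- make_barrel_trajectory(spec)
  t2 <- make_barrel_trajectory(spec)
  for (i in 1:3) expect_identical(frame_coords(t1[[i]]), frame_coords(t2[[i]]))
  t3 <- make_barrel_trajectory(barrel_spec(n_wall_atoms = 300, n_cap_atoms = 30,
                                           n_frames = 3, seed = 22))
  expect_false(identical(frame_coords(t3[[2]]), frame_coords(t1[[2]])))
  # the generator leaves the caller's RNG stream untouched
  withr::with_seed(99, {
    before <- runif(1)
  })
  withr::with_seed(99, {
    make_barrel_trajectory(spec)
    expect_equal(runif(1), before)
  })
})

test_that("zero jitter reproduces frame 1 and a zero-sigma grid downstream", {
  spec <- barrel_spec(n_wall_atoms = 200, n_cap_atoms = 20, n_frames = 3,
                      jitter_sd = 0, seed = 23)
  traj <- make_barrel_trajectory(spec)
  expect_identical(frame_coords(traj[[2]]), frame_coords(traj[[1]]))
  gspec <- grid_spec(c(16, 16, 16), box = spec$box, center = spec$box / 2)
  grids <- lapply(1:3, function(i) pme_reciprocal_grid(traj[[i]], gspec))
  st <- accumulate_stats(grids)
  expect_lt(max(st$sigma), 1e-10 * max(abs(st$mean)))
})

test_that("the declared cavity contains no atom in any frame", {
  spec <- barrel_spec(n_wall_atoms = 500, n_cap_atoms = 50, n_frames = 5, seed = 24)
  traj <- make_barrel_trajectory(spec)
  cavity <- attr(traj, "truth")$cavity
  for (i in seq_along(traj$frames)) {
    expect_false(any(point_in_ellipsoid(traj[[i]], cavity)))
  }
  # frame 1 is the unjittered geometry: wall atoms sit exactly on the cylinder
  f1 <- traj[[1]]
  wall <- f1[f1$atom == "W", ]
  r <- sqrt((wall$x - spec$box[1] / 2)^2 + (wall$y - spec$box[2] / 2)^2)
  expect_lt(max(abs(r - spec$radius)), 1e-9)
  # total charge is neutral by construction
  expect_lt(abs(sum(f1$charge)), 1e-9)
})

test_that("inscription succeeds on the barrel with near-cylinder semi-axes", {
  spec <- barrel_spec(n_wall_atoms = 1500, n_cap_atoms = 150, n_frames = 1, seed = 25)
  traj <- make_barrel_trajectory(spec)
  e <- inscribe_ellipsoid(traj[[1]])
  # x/y semi-axes reach the wall radius minus margin and discretization
  expect_gt(min(e$radii[1:2]), spec$radius - 3)
  expect_lt(max(e$radii[1:2]), spec$radius)
  expect_gt(e$radii[3], 5)
})

test_that("planted grids carry the truth field and the designed sigma structure", {
  truth <- polynomial_model(c(2, -0.05, 0.1, 0.16), order = 1)
  gspec <- grid_spec(c(12, 12, 12), box = c(24, 24, 24), center = c(0, 0, 0))
  noiseless <- make_planted_gridstats(
    planted_grid_spec(truth, gspec, noise_sd = 0, n_frames = 10, seed = 26))
  pts <- grid_points(gspec)
  expect_lt(max(abs(as.vector(noiseless$mean) -
                      evaluate_potential(truth, pts))), 1e-12)
  expect_true(all(noiseless$sigma == 0))
  e <- ellipsoid(c(0, 0, 0), c(9, 9, 9))
  cp <- select_control_points(noiseless, e, sigma_max = 0.5)
  fit <- fit_potential(cp, order = 1)
  expect_lt(max(abs(fit$terms$estimate - truth$terms$estimate)), 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # heteroscedastic sigma: the filter removes exactly the noisy sub-region
  noisy_region <- function(x, y, z) ifelse(x > 0 & z > 0, 0.5, 0.1)
  st <- make_planted_gridstats(
    planted_grid_spec(truth, gspec, noise_sd = noisy_region,
                      n_frames = 100, seed = 27))
  cp2 <- select_control_points(st, e, sigma_max = 0.3)
  inside <- pts[point_in_ellipsoid(pts, e), ]
  expect_setequal(paste(cp2$x, cp2$y, cp2$z),
                  paste(inside$x, inside$y, inside$z)[!(inside$x > 0 & inside$z > 0)])
  # determinism
  st2 <- make_planted_gridstats(
    planted_grid_spec(truth, gspec, noise_sd = noisy_region,
                      n_frames = 100, seed = 27))
  expect_identical(st$mean, st2$mean)
})

test_that("planted linear coefficients are recovered within 3 analytic SEs", {
  ref <- hsp60_cavity()
  gspec <- grid_spec(c(40, 40, 32), box = c(64, 64, 52), center = ref$ellipsoid$center)
  st <- make_planted_gridstats(
    planted_grid_spec(ref$model_linear, gspec, noise_sd = 0.3,
                      n_frames = 1, seed = 28))
  e <- ellipsoid(ref$ellipsoid$center, c(28, 28, 22))
  cp <- select_control_points(st, e, sigma_max = 1)
  expect_gte(nrow(cp), 1e4)
  fit <- fit_potential(cp, order = 1)
  z <- (fit$terms$estimate - ref$model_linear$terms$estimate) / fit$std_error
  expect_lt(max(abs(z)), 3)
})

test_that("the synthetic reference surrogate reproduces the published fits", {
  cp <- make_reference_control_points(seed = 29)
  ref <- hsp60_cavity()
  # counts match the published selection to a few percent
  expect_lt(abs(attr(cp, "n_inside") - ref$n_inside) / ref$n_inside, 0.01)
  removed <- percent_removed(attr(cp, "n_inside"), attr(cp, "n_kept"))
  expect_lt(abs(removed - 8.4), 1)
  f1 <- fit_potential(cp, order = 1)
  f2 <- fit_potential(cp, order = 2)
  expect_equal(f1$r_squared, ref$r_squared[["order1"]], tolerance = 0.02)
  expect_equal(f2$r_squared, ref$r_squared[["order2"]], tolerance = 0.02)
  expect_equal(f1$terms$estimate[4], 1.6188e-1, tolerance = 0.02)
})
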