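# small deterministic fixtures, built in code at test time

tiny_frame <- function() {
  charge_frame(tibble::tibble(
    atom = c("N", "C", "O"), resname = "GLY", resid = "1",
    x = c(0, 1.5, 3.0), y = c(0, 0.5, -0.5), z = c(0, 1, 2),
    charge = c(1, -1, 0), radius = c(1.6, 1.7, 1.5)
  ))
}

random_frame <- function(n = 8, seed = 42, box = c(60, 60, 60)) {
  withr::with_seed(seed, {
    q <- rnorm(n)
    q <- q - mean(q)  # neutral
    charge_frame(tibble::tibble(
      x = runif(n, 0.2 * box[1], 0.8 * box[1]),
      y = runif(n, 0.2 * box[2], 0.8 * box[2]),
      z = runif(n, 0.2 * box[3], 0.8 * box[3]),
      charge = q
    ))
  })
}

cube_spec <- function(n = 32, l = 60) {
  grid_spec(rep(n, 3), box = rep(l, 3), center = rep(l / 2, 3))
}

# points on a sphere shell plus a flat base below it, as a charge frame
sphere_shell_frame <- function(n = 500, radius = 30, seed = 7, base_n = 200) {
  withr::with_seed(seed, {
    u <- matrix(rnorm(n * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * radius
    base <- cbind(runif(base_n, -radius, radius),
                  runif(base_n, -radius, radius), -radius)
    xyz <- rbind(u, base)
    charge_frame(tibble::tibble(
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = 0
    ))
  })
}

rigid_motion <- function(xyz, angle = pi / 2, axis = "z", shift = c(5, 0, 0)) {
  ca <- cos(angle); sa <- sin(angle)
  r <- switch(axis,
              z = matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE),
              x = matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE))
  sweep(xyz %*% t(r), 2, shift, `+`)
}

frame_from_matrix <- function(m, charge = 0) {
  charge_frame(tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3],
                              charge = rep_len(charge, nrow(m))))
}
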