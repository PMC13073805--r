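#' Particle-mesh Ewald parameters
#'
#' `ewald_beta` is the Gaussian splitting parameter (inverse smearing width,
#' 1/Å); the reciprocal-space potential computed here is the electrostatic
#' potential of the Gaussian-smoothed charge density. `spline_order` is the
#' cardinal B-spline interpolation order used to spread charges onto the
#' mesh. `kmax` bounds the direct reciprocal sum in
#' [ewald_reciprocal_direct()] (integer wave-vector components).
#'
#' Defaults follow the documented defaults of the standard PME potential
#' mapping plugin: beta = 0.25 1/Å, order 4.
#'
#' @param ewald_beta Splitting parameter in 1/Å; > 0.
#' @param spline_order Even B-spline order, one of 4, 6, 8.
#' @param kmax Integer cutoff for the direct k-space sum; >= 1.
#' @return A `pme_params` object.
#' @export
pme_params <- function(ewald_beta = 0.25, spline_order = 4, kmax = 20) {
  if (!is.numeric(ewald_beta) || ewald_beta <= 0) abort("ewald_beta must be > 0")
  if (!spline_order %in% c(4, 6, 8)) abort("spline_order must be 4, 6 or 8")
  if (kmax < 1) abort("kmax must be >= 1")
  structure(list(ewald_beta = ewald_beta,
                 spline_order = as.integer(spline_order),
                 kmax = as.integer(kmax)),
            class = "pme_params")
}

# Cardinal B-spline M_n(x), support (0, n), by the stable two-term recursion.
bspline_m <- function(x, n) {
  if (n == 2) return(pmax(0, 1 - abs(x - 1)))
  xm <- bspline_m(x, n - 1)
  xm1 <- bspline_m(x - 1, n - 1)
  (x * xm + (n - x) * xm1) / (n - 1)
}

# Euler spline deconvolution factor per axis: C(m) = sum_j M_p(j) e^{2*pi*i*m*j/n},
# j = 1..p-1. FFT(Q)(m) ~ S(m) * C(m) for each axis, so dividing by C recovers
# the structure factor of the point charges from the spread mesh charge.
spline_dft_factor <- function(n, p) {
  m <- 0:(n - 1)
  j <- 1:(p - 1)
  w <- bspline_m(j, p)
  acc <- complex(real = rep(0, n), imaginary = rep(0, n))
  for (s in seq_along(j)) {
    acc <- acc + w[s] * exp(2i * pi * m * j[s] / n)
  }
  acc
}

# signed integer frequencies for an n-point DFT, in fft output order
signed_freq <- function(n) {
  m <- 0:(n - 1)
  ifelse(m > n / 2, m - n, m)
}

# Coulomb constant in (kT at 300 K / e) * Å per e: e/(4 pi eps0 Å) / (kB*300/e)
coulomb_kt300 <- function() {
  e <- 1.602176634e-19
  kb <- 1.380649e-23
  eps0 <- 8.8541878128e-12
  (e / (4 * pi * eps0 * 1e-10)) / (kb * 300 / e)
}

#' Reciprocal-space Ewald potential of one frame on a periodic grid
#'
#' Computes the long-range term of the Ewald/PME decomposition — the periodic
#' electrostatic potential of Gaussian-smeared charges — sampled at every
#' grid node, via smooth particle-mesh Ewald: charges are wrapped into the
#' orthorhombic cell, spread onto the mesh with cardinal B-splines, Fourier
#' transformed, multiplied by the influence function
#' `exp(-k^2/(4 beta^2))/k^2` (with the k = 0 term dropped, i.e. tinfoil
#' boundary: the potential is defined up to an additive constant), spline
#' deconvolved, and transformed back. Values are in units of kT/e at 300 K.
#'
#' @param frame A [charge_frame()].
#' @param spec A [grid_spec()]; the periodic cell equals the grid box.
#' @param pme A [pme_params()].
#' @return A [potential_grid()] in `kT300_per_e` units.
#' @seealso [ewald_reciprocal_direct()] for the brute-force k-sum this
#'   routine is validated against.
#' @export
pme_reciprocal_grid <- function(frame, spec, pme = pme_params()) {
  stopifnot(inherits(spec, "grid_spec"))
  n <- spec$counts
  p <- pme$spline_order
  if (any(n < p)) abort("grid counts must be >= spline_order along every axis")
  if (any(n < 8)) abort("PME needs at least 8 grid points per axis")
  q <- frame$charge
  if (all(q == 0)) {
    return(potential_grid(spec, array(0, dim = n), units = "kT300_per_e"))
  }
  xyz <- frame_coords(frame)
  o <- grid_origin(spec)
  # fractional mesh coordinates, wrapped into [0, n)
  u <- sweep(sweep(xyz, 2, o), 2, spec$spacing, `/`)
  u <- sweep(u, 2, n, function(a, b) a %% b)

  mesh_q <- array(0, dim = n)
  idx_w <- lapply(1:3, function(d) spread_stencil(u[, d], n[d], p))
  # combine per-axis stencils into p^3 contributions per atom
  pa <- rep(seq_len(p), times = p * p)
  pb <- rep(rep(seq_len(p), each = p), times = p)
  pc <- rep(seq_len(p), each = p * p)
  w <- idx_w[[1]]$w[, pa] * idx_w[[2]]$w[, pb] * idx_w[[3]]$w[, pc]
  lin <- idx_w[[1]]$i[, pa] +
    (idx_w[[2]]$i[, pb] - 1L) * n[1] +
    (idx_w[[3]]$i[, pc] - 1L) * n[1] * n[2]
  contrib <- rowsum(as.vector(q * w), group = as.vector(lin))
  mesh_q[as.integer(rownames(contrib))] <- contrib

  fq <- fft(mesh_q)
  # deconvolve the B-spline spreading per axis
  cx <- spline_dft_factor(n[1], p)
  cy <- spline_dft_factor(n[2], p)
  cz <- spline_dft_factor(n[3], p)
  denom <- outer(outer(cx, cy), cz)
  g <- influence_function(spec, pme$ewald_beta)
  phi_hat <- g * fq / denom
  phi <- Re(fft(phi_hat, inverse = TRUE))
  pref <- 4 * pi * coulomb_kt300() / prod(spec$box)
  potential_grid(spec, pref * phi, units = "kT300_per_e")
}

# per-axis spreading stencil: p mesh indices (1-based, wrapped) and weights
spread_stencil <- function(u, n, p) {
  k0 <- floor(u)
  offs <- seq(0, p - 1)
  k <- outer(k0, rep(1, p)) - matrix(offs, nrow = length(u), ncol = p, byrow = TRUE)
  w <- bspline_m(u - k, p)
  i <- (k %% n) + 1L
  storage.mode(i) <- "integer"
  list(i = i, w = w)
}

influence_function <- function(spec, beta) {
  n <- spec$counts
  kx <- 2 * pi * signed_freq(n[1]) / spec$box[1]
  ky <- 2 * pi * signed_freq(n[2]) / spec$box[2]
  kz <- 2 * pi * signed_freq(n[3]) / spec$box[3]
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  g <- array(0, dim = n)
  nz <- k2 > 0
  g[nz] <- exp(-k2[nz] / (4 * beta^2)) / k2[nz]
  g
}

#' Direct reciprocal-space Ewald sum at arbitrary points
#'
#' Brute-force oracle for [pme_reciprocal_grid()]: evaluates the Gaussian
#' smeared periodic potential as an explicit sum over reciprocal lattice
#' vectors `k = 2*pi*(mx/Lx, my/Ly, mz/Lz)` with integer components
#' `|m| <= kmax` (k = 0 excluded),
#' `phi(r) = (4*pi*C/V) * sum_k exp(-k^2/(4 beta^2))/k^2 * sum_j q_j cos(k.(r - r_j))`,
#' where C converts to kT/e at 300 K — the same units and k = 0 convention
#' as the mesh route.
#'
#' @param frame A [charge_frame()].
#' @param spec A [grid_spec()] (supplies the periodic cell).
#' @param pme A [pme_params()] (`ewald_beta`, `kmax`).
#' @param points Matrix or data frame of evaluation points (Å).
#' @return Numeric vector of potentials in kT300/e.
#' @export
ewald_reciprocal_direct <- function(frame, spec, pme, points) {
  stopifnot(inherits(spec, "grid_spec"))
  if (pme$kmax < 1) abort("kmax must be >= 1")
  pts <- as.matrix(as.data.frame(points)[, 1:3])
  storage.mode(pts) <- "double"
  q <- frame$charge
  if (all(q == 0)) return(rep(0, nrow(pts)))
  xyz <- frame_coords(frame)
  km <- pme$kmax
  m <- as.matrix(expand.grid(mx = -km:km, my = -km:km, mz = -km:km))
  m <- m[rowSums(m^2) > 0, , drop = FALSE]
  kvec <- t(t(m) * (2 * pi / spec$box))
  k2 <- rowSums(kvec^2)
  g <- exp(-k2 / (4 * pme$ewald_beta^2)) / k2
  phase_atoms <- kvec %*% t(xyz)          # n_k x n_atoms
  s_re <- cos(phase_atoms) %*% q
  s_im <- sin(phase_atoms) %*% q
  phase_pts <- kvec %*% t(pts)            # n_k x n_points
  # sum_j q_j cos(k.(r - r_j)) = cos(k.r) sum q cos(k.r_j) + sin(k.r) sum q sin(k.r_j)
  acc <- crossprod(cos(phase_pts), g * s_re) + crossprod(sin(phase_pts), g * s_im)
  pref <- 4 * pi * coulomb_kt300() / prod(spec$box)
  as.numeric(pref * acc)
}
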