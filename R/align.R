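#' Rigid-body superposition of a trajectory onto a reference frame
#'
#' Each frame is rotated and translated onto the reference frame by optimal
#' unweighted least-squares superposition (Kabsch algorithm; proper rotations
#' only, no reflection). The returned RMSD is the post-fit all-atom value.
#'
#' @param traj A `charge_trajectory`.
#' @param ref_index Index of the reference frame (default 1).
#' @return The aligned trajectory, with a numeric attribute `rmsd` (Å, one
#'   value per frame).
#' @export
align_to_reference <- function(traj, ref_index = 1) {
  stopifnot(inherits(traj, "charge_trajectory"))
  nf <- length(traj$frames)
  if (ref_index < 1 || ref_index > nf) abort("ref_index out of range")
  ref <- frame_coords(traj$frames[[ref_index]])
  if (nrow(ref) < 3) abort("superposition needs at least 3 atoms")
  check_not_collinear(ref)
  ref_c <- frame_center(ref)
  ref0 <- sweep(ref, 2, ref_c)
  rmsd <- numeric(nf)
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    mob <- frame_coords(traj$frames[[i]])
    fit <- kabsch(mob, ref0, ref_c)
    frames[[i]] <- with_coords(traj$frames[[i]], fit$coords)
    rmsd[i] <- fit$rmsd
  }
  out <- as_trajectory(frames)
  attr(out, "rmsd") <- rmsd
  attr(out, "ref_index") <- ref_index
  out
}

# mob: raw mobile coords; ref0: centered reference; ref_c: reference centroid
kabsch <- function(mob, ref0, ref_c) {
  mob_c <- colMeans(mob)
  mob0 <- sweep(mob, 2, mob_c)
  h <- crossprod(mob0, ref0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(mob0 %*% t(rot), 2, ref_c, `+`)
  dev <- fitted - sweep(ref0, 2, ref_c, `+`)
  list(coords = fitted, rmsd = sqrt(mean(rowSums(dev^2))))
}

check_not_collinear <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(c0, nu = 0, nv = 0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1e-30)) {
    abort("reference atoms are collinear; superposition is degenerate")
  }
  invisible(TRUE)
}
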