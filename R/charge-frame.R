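#' Charge frames: one snapshot of a partial-charge model
#'
#' A charge frame is a tibble with one row per atom and at least the columns
#' `x`, `y`, `z` (coordinates, Å) and `charge` (partial charge, e). The
#' optional columns `radius` (Å), `atom`, `resname` and `resid` are carried
#' through from PQR input when present. Frames are ordinary tibbles, so all
#' dplyr verbs apply; the class tag only buys validation and printing.
#'
#' @param x A data frame with at least `x`, `y`, `z`, `charge` columns.
#' @param frame_time Optional time stamp in ps.
#' @return A `charge_frame` tibble.
#' @examples
#' charge_frame(data.frame(x = 0, y = 0, z = 1, charge = -1))
#' @export
charge_frame <- function(x, frame_time = NULL) {
  x <- as_tibble(x)
  required <- c("x", "y", "z", "charge")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("charge_frame needs columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) abort("charge_frame must contain at least one atom")
  num <- x[required]
  if (!all(vapply(num, is.numeric, logical(1)))) {
    abort("x, y, z and charge must be numeric")
  }
  if (!all(is.finite(as.matrix(num)))) {
    abort("positions and charges must be finite")
  }
  if (!is.null(x[["radius"]])) {
    bad <- is.finite(x$radius) & x$radius < 0
    if (any(bad)) abort("radii must be >= 0")
  }
  class(x) <- c("charge_frame", class(x))
  attr(x, "frame_time") <- frame_time
  x
}

#' @export
print.charge_frame <- function(x, ...) {
  cat(sprintf("<charge_frame> %d atoms, net charge %.4f e\n", nrow(x), sum(x$charge)))
  NextMethod()
}

is_charge_frame <- function(x) inherits(x, "charge_frame")

#' Atom coordinates of a charge frame as a matrix
#'
#' @param frame A [charge_frame()].
#' @return An n-by-3 numeric matrix with columns x, y, z (Å).
#' @export
frame_coords <- function(frame) {
  stopifnot(is.data.frame(frame))
  cbind(x = frame$x, y = frame$y, z = frame$z)
}

#' Geometric center of a charge frame
#'
#' The unweighted centroid of the atom positions. PQR-style inputs carry no
#' atomic masses, so the centroid stands in for the center of mass throughout
#' the pipeline (superposition is likewise unit-weighted).
#'
#' @param frame A [charge_frame()] or coordinate matrix.
#' @return Length-3 numeric vector (Å).
#' @export
frame_center <- function(frame) {
  xyz <- if (is.matrix(frame)) frame else frame_coords(frame)
  colMeans(xyz)
}

with_coords <- function(frame, xyz) {
  frame$x <- xyz[, 1]
  frame$y <- xyz[, 2]
  frame$z <- xyz[, 3]
  frame
}

#' Trajectories: an ordered list of charge frames
#'
#' Every frame must have the same atom count and ordering. Charges are taken
#' from the frames themselves (they are usually broadcast from a single charge
#' source by [read_trajectory()] or the synthetic generator).
#'
#' @param frames A list of [charge_frame()] objects.
#' @return A `charge_trajectory` object.
#' @export
as_trajectory <- function(frames) {
  if (length(frames) < 1) abort("a trajectory needs at least one frame")
  frames <- lapply(frames, function(f) if (is_charge_frame(f)) f else charge_frame(f))
  counts <- vapply(frames, nrow, integer(1))
  if (length(unique(counts)) != 1) {
    abort(sprintf(
      "all frames must have the same atom count (saw %s)",
      paste(unique(counts), collapse = ", ")
    ))
  }
  structure(list(frames = frames), class = "charge_trajectory")
}

#' @export
length.charge_trajectory <- function(x) length(x$frames)

#' @export
`[[.charge_trajectory` <- function(x, i) x$frames[[i]]

#' @export
print.charge_trajectory <- function(x, ...) {
  cat(sprintf(
    "<charge_trajectory> %d frames x %d atoms\n",
    length(x$frames), nrow(x$frames[[1]])
  ))
  invisible(x)
}

n_atoms <- function(traj) nrow(traj$frames[[1]])
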