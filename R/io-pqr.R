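#' Read a PQR file into a charge frame
#'
#' Parses the whitespace-delimited PQR dialect written by pdb2pqr: every
#' `ATOM`/`HETATM` record ends in the five numeric fields
#' `x y z charge radius`. Records are kept in file order; nothing is dropped
#' silently — a malformed record raises an error naming its line number.
#'
#' @param path Path to a PQR file.
#' @return A [charge_frame()] with columns `atom`, `resname`, `resid`,
#'   `x`, `y`, `z` (Å), `charge` (e), `radius` (Å).
#' @seealso [write_pqr()]
#' @export
read_pqr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM|HETATM)", lines)
  if (!any(sel)) abort(sprintf("no ATOM/HETATM records found in '%s'", path))
  idx <- which(sel)
  parts <- strsplit(trimws(lines[sel]), "\\s+")
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 9)) {
    abort(sprintf(
      "malformed PQR record on line %d of '%s' (fewer than 9 fields)",
      idx[which(nf < 9)[1]], path
    ))
  }
  # the last five whitespace fields are x y z charge radius; name/resname/resid
  # sit in fixed early fields (chain id optional, hence parse from the right)
  take <- function(k) vapply(parts, function(p) p[length(p) - k], character(1))
  num <- lapply(4:0, function(k) suppressWarnings(as.numeric(take(k))))
  names(num) <- c("x", "y", "z", "charge", "radius")
  for (col in names(num)) {
    bad <- which(!is.finite(num[[col]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric %s field on line %d of '%s'", col, idx[bad[1]], path
      ))
    }
  }
  charge_frame(tibble(
    atom = vapply(parts, `[`, character(1), 3),
    resname = vapply(parts, `[`, character(1), 4),
    resid = vapply(parts, function(p) p[length(p) - 5], character(1)),
    x = num$x, y = num$y, z = num$z,
    charge = num$charge, radius = num$radius
  ))
}

#' Write a charge frame as whitespace-delimited PQR
#'
#' Coordinates are printed at 3 decimals, charges and radii at 4, matching
#' the precision of pdb2pqr output; [read_pqr()] round-trips these values.
#'
#' @param frame A [charge_frame()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(frame, path) {
  frame <- if (is_charge_frame(frame)) frame else charge_frame(frame)
  n <- nrow(frame)
  atom <- frame[["atom"]] %||% rep("X", n)
  resname <- frame[["resname"]] %||% rep("UNK", n)
  resid <- frame[["resid"]] %||% rep("1", n)
  radius <- frame[["radius"]] %||% rep(0, n)
  rec <- sprintf(
    "ATOM  %5d %-4s %-4s %5s    %8.3f %8.3f %8.3f %8.4f %7.4f",
    seq_len(n), atom, resname, resid,
    frame$x, frame$y, frame$z, frame$charge, radius
  )
  writeLines(rec, path)
  invisible(path)
}

#' Read a multi-frame trajectory with a per-atom charge source
#'
#' Accepts either a multi-model PDB (`MODEL`/`ENDMDL` blocks, fixed-column
#' coordinates) together with an external charge source, or a concatenated
#' multi-model PQR in which each model carries its own charges. All models
#' must have identical atom counts; charges from the source are broadcast to
#' every frame by atom position.
#'
#' @param path Path to a multi-model PDB or PQR file.
#' @param charges A [charge_frame()], a data frame with a `charge` column, or
#'   a numeric vector; required for PDB input, ignored for PQR input.
#' @param format `"pdb"`, `"pqr"`, or `"auto"`: decide from the file
#'   extension, falling back to a content heuristic (PDB records carry
#'   fixed-column occupancy/B-factor fields past column 54).
#' @return A `charge_trajectory`.
#' @export
read_trajectory <- function(path, charges = NULL, format = c("auto", "pdb", "pqr")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "pqr") "pqr"
    else if (ext %in% c("pdb", "ent")) "pdb"
    else if (pqr_like(lines)) "pqr"
    else "pdb"
  }
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    # single block: treat the whole file as one model
    blocks <- list(lines)
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      abort(sprintf("unbalanced MODEL/ENDMDL records in '%s'", path))
    }
    blocks <- Map(function(s, e) lines[(s + 1):(e - 1)], model_starts, model_ends)
  }
  is_pqr <- format == "pqr"
  frames <- lapply(seq_along(blocks), function(i) {
    block <- blocks[[i]]
    rec <- block[grepl("^(ATOM|HETATM)", block)]
    if (length(rec) == 0) abort(sprintf("model %d of '%s' holds no atoms", i, path))
    if (is_pqr) parse_pqr_records(rec, path) else parse_pdb_records(rec)
  })
  counts <- vapply(frames, nrow, integer(1))
  if (length(unique(counts)) != 1) {
    abort(sprintf(
      "models in '%s' have differing atom counts: %s",
      path, paste(unique(counts), collapse = " vs ")
    ))
  }
  if (!is_pqr) {
    if (is.null(charges)) {
      abort("PDB input carries no charges; supply `charges` (a charge frame, data frame or vector)")
    }
    qr_ <- charge_source(charges, counts[1])
    frames <- lapply(frames, function(f) {
      f$charge <- qr_$charge
      f$radius <- qr_$radius
      charge_frame(f)
    })
  } else {
    frames <- lapply(frames, charge_frame)
  }
  as_trajectory(frames)
}

pqr_like <- function(lines) {
  rec <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (length(rec) == 0) return(FALSE)
  p <- strsplit(trimws(rec[1]), "\\s+")[[1]]
  # PQR rows parse whole-line as whitespace fields ending in 5 numerics
  if (length(p) < 9) return(FALSE)
  tailing <- suppressWarnings(as.numeric(p[(length(p) - 4):length(p)]))
  all(is.finite(tailing))
}

parse_pqr_records <- function(rec, path) {
  tmp <- tempfile(fileext = ".pqr")
  on.exit(unlink(tmp))
  writeLines(rec, tmp)
  read_pqr(tmp)
}

parse_pdb_records <- function(rec) {
  num <- function(from, to) suppressWarnings(as.numeric(substr(rec, from, to)))
  out <- tibble(
    atom = trimws(substr(rec, 13, 16)),
    resname = trimws(substr(rec, 18, 20)),
    resid = trimws(substr(rec, 23, 26)),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    charge = 0
  )
  bad <- which(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))
  if (length(bad) > 0) {
    abort(sprintf("malformed PDB coordinate record: '%s'", rec[bad[1]]))
  }
  out
}

charge_source <- function(charges, n) {
  if (is.numeric(charges)) {
    q <- charges
    r <- rep(0, length(q))
  } else if (is.data.frame(charges)) {
    if (is.null(charges[["charge"]])) abort("charge source has no `charge` column")
    q <- charges$charge
    r <- charges[["radius"]] %||% rep(0, nrow(charges))
  } else {
    abort("`charges` must be a charge frame, data frame or numeric vector")
  }
  if (length(q) != n) {
    abort(sprintf("charge source has %d atoms but models have %d", length(q), n))
  }
  list(charge = q, radius = r)
}

#' Write a trajectory as a multi-model PDB
#'
#' Coordinates are written in the fixed PDB columns at 3 decimals, so a
#' round trip through [read_trajectory()] reproduces positions to 1e-3 Å.
#'
#' @param traj A `charge_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    n <- nrow(f)
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s  %4s    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(n) %% 100000,
      substr(f[["atom"]] %||% rep("X", n), 1, 4),
      substr(f[["resname"]] %||% rep("UNK", n), 1, 3),
      substr(f[["resid"]] %||% rep("1", n), 1, 4),
      f$x, f$y, f$z
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
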