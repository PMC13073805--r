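#' Write a scalar grid in OpenDX format
#'
#' Emits a "regular positions, regular connections" scalar field, the format
#' produced by PME potential mapping tools and read by VMD/PyMOL. Data runs
#' z-fastest (x slowest), per the OpenDX convention. The grid units are noted
#' in a comment line that [read_grid_dx()] recovers.
#'
#' @param grid A [potential_grid()] or [grid_stats()].
#' @param path Output path.
#' @param component For `grid_stats` input, which field to write:
#'   `"mean"` or `"sigma"`.
#' @return `path`, invisibly.
#' @export
write_grid_dx <- function(grid, path, component = c("mean", "sigma")) {
  if (inherits(grid, "grid_stats")) {
    component <- match.arg(component)
    values <- grid[[component]]
    spec <- grid$spec
    units <- grid$units
  } else if (inherits(grid, "potential_grid")) {
    values <- grid$values
    spec <- grid$spec
    units <- grid$units
  } else {
    abort("write_grid_dx expects a potential_grid or grid_stats")
  }
  n <- spec$counts
  o <- grid_origin(spec)
  d <- spec$spacing
  flat <- as.vector(aperm(values, c(3, 2, 1)))  # z fastest
  total <- length(flat)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# OpenDX scalar field written by cavityfield (units: %s)", units),
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.9g %.9g %.9g", o[1], o[2], o[3]),
    sprintf("delta %.9g 0 0", d[1]),
    sprintf("delta 0 %.9g 0", d[2]),
    sprintf("delta 0 0 %.9g", d[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", total)
  ), con)
  full_rows <- total %/% 3
  body <- character(0)
  if (full_rows > 0) {
    m <- matrix(formatC(flat[seq_len(full_rows * 3)], format = "g", digits = 9),
                ncol = 3, byrow = TRUE)
    body <- paste(m[, 1], m[, 2], m[, 3])
  }
  rem <- total - full_rows * 3
  if (rem > 0) {
    body <- c(body, paste(formatC(flat[(full_rows * 3 + 1):total],
                                  format = "g", digits = 9), collapse = " "))
  }
  writeLines(body, con)
  writeLines(c(
    'attribute "dep" string "positions"',
    'object "regular positions regular connections" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3'
  ), con)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' @param path Path to a `.dx` file with regular positions/connections.
#' @param units Units to tag the grid with when the file carries no units
#'   comment.
#' @return A [potential_grid()].
#' @export
read_grid_dx <- function(path, units = NULL) {
  lines <- readLines(path, warn = FALSE)
  umatch <- regmatches(lines, regexpr("units: [A-Za-z0-9_]+", lines))
  if (is.null(units)) {
    units <- if (length(umatch) > 0) sub("units: ", "", umatch[[1]]) else "volt"
  }
  gp <- grep("class gridpositions counts", lines, value = TRUE)
  if (length(gp) == 0) abort(sprintf("'%s' is not an OpenDX regular grid", path))
  counts <- as.integer(strsplit(trimws(sub(".*counts", "", gp[1])), "\\s+")[[1]])
  if (length(counts) != 3 || any(is.na(counts))) {
    abort(sprintf("cannot parse grid counts in '%s'", path))
  }
  origin_line <- grep("^origin", lines, value = TRUE)
  if (length(origin_line) == 0) abort(sprintf("missing origin in '%s'", path))
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", origin_line[1])), "\\s+")[[1]])
  delta_lines <- grep("^delta", lines, value = TRUE)
  if (length(delta_lines) < 3) abort(sprintf("missing delta rows in '%s'", path))
  deltas <- t(vapply(delta_lines[1:3], function(l) {
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]])
  }, numeric(3)))
  if (any(abs(deltas[upper.tri(deltas) | lower.tri(deltas)]) > 1e-12)) {
    abort("only axis-aligned (diagonal delta) grids are supported")
  }
  spacing <- diag(deltas)
  data_start <- grep("data follows", lines)
  if (length(data_start) == 0) abort(sprintf("missing data section in '%s'", path))
  items <- as.integer(sub(".*items\\s+(\\d+)\\s+data follows.*", "\\1", lines[data_start[1]]))
  expected <- prod(counts)
  if (items != expected) {
    abort(sprintf("item count %d does not match grid counts (%d)", items, expected))
  }
  body <- lines[(data_start[1] + 1):length(lines)]
  body <- body[!grepl("^(attribute|object|component|#)", body) & nzchar(trimws(body))]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+"), use.names = FALSE))
  if (length(vals) != expected || any(is.na(vals))) {
    abort(sprintf("expected %d numeric values in '%s', found %d valid",
                  expected, path, sum(!is.na(vals))))
  }
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))  # file is z-fastest
  box <- spacing * counts
  spec <- grid_spec(counts, box, center = origin + box / 2)
  potential_grid(spec, arr, units = units)
}
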