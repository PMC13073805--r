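#' Write control points as CSV
#'
#' Columns are `x`, `y`, `z` (Å), `phi` (mean long-range potential, V) and
#' `sigma` (its temporal standard deviation, V), printed at 6 significant
#' digits. Selection provenance (ellipsoid, threshold, counts), when present,
#' is stored in leading comment lines so [read_control_points()] can restore
#' it.
#'
#' @param points A control-point tibble (see [select_control_points()]) or
#'   any data frame with the five columns above.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_control_points <- function(points, path) {
  required <- c("x", "y", "z", "phi", "sigma")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0) {
    abort(paste0("control points need columns: ", paste(missing_cols, collapse = ", ")))
  }
  header <- character(0)
  prov <- control_point_provenance(points)
  if (!is.null(prov$ellipsoid)) {
    e <- prov$ellipsoid
    header <- c(header, sprintf(
      "# ellipsoid center %.9g %.9g %.9g radii %.9g %.9g %.9g",
      e$center[1], e$center[2], e$center[3], e$radii[1], e$radii[2], e$radii[3]
    ))
  }
  if (!is.null(prov$sigma_max)) {
    header <- c(header, sprintf("# sigma_max %.9g", prov$sigma_max))
  }
  if (!is.null(prov$n_inside)) {
    header <- c(header, sprintf("# n_inside %d n_kept %d", prov$n_inside, prov$n_kept))
  }
  out <- dplyr::mutate(
    as_tibble(points)[required],
    dplyr::across(dplyr::everything(), ~ signif(.x, 6))
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header) > 0) writeLines(header, con)
  writeLines(paste(required, collapse = ","), con)
  writeLines(do.call(paste, c(lapply(out, format_sig6), list(sep = ","))), con)
  invisible(path)
}

format_sig6 <- function(x) formatC(x, format = "g", digits = 6)

#' Read a control-point CSV
#'
#' @param path Path written by [write_control_points()] (or any CSV with
#'   columns x, y, z, phi, sigma).
#' @return A `control_points` tibble with provenance attributes when the
#'   file carries them.
#' @export
read_control_points <- function(path) {
  head_lines <- readLines(path, n = 10, warn = FALSE)
  comments <- head_lines[grepl("^#", head_lines)]
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  required <- c("x", "y", "z", "phi", "sigma")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("'%s' is missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (!all(is.finite(as.matrix(df[required])))) {
    abort(sprintf("non-finite control-point values in '%s'", path))
  }
  out <- as_tibble(df[required])
  ell_line <- grep("^# ellipsoid", comments, value = TRUE)
  if (length(ell_line) > 0) {
    v <- as.numeric(strsplit(ell_line[1], "\\s+")[[1]][c(4:6, 8:10)])
    attr(out, "ellipsoid") <- ellipsoid(center = v[1:3], radii = v[4:6])
  }
  sm_line <- grep("^# sigma_max", comments, value = TRUE)
  if (length(sm_line) > 0) {
    attr(out, "sigma_max") <- as.numeric(strsplit(sm_line[1], "\\s+")[[1]][3])
  }
  ct_line <- grep("^# n_inside", comments, value = TRUE)
  if (length(ct_line) > 0) {
    v <- strsplit(ct_line[1], "\\s+")[[1]]
    attr(out, "n_inside") <- as.integer(v[3])
    attr(out, "n_kept") <- as.integer(v[5])
  }
  class(out) <- c("control_points", class(out))
  out
}

control_point_provenance <- function(points) {
  list(
    ellipsoid = attr(points, "ellipsoid"),
    sigma_max = attr(points, "sigma_max"),
    n_inside = attr(points, "n_inside"),
    n_kept = attr(points, "n_kept")
  )
}
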