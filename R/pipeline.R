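#' Pipeline configuration
#'
#' Exactly one entry point must be set: a trajectory (with a charge source),
#' precomputed mean/sigma grids, or a control-point set. Later stages run
#' regardless of the entry point; earlier ones are skipped. All stages are
#' pure: the same inputs produce the same artifacts.
#'
#' @param trajectory Path to a multi-model PDB/PQR, or a `charge_trajectory`.
#' @param charges Charge source for PDB trajectories (path to PQR, charge
#'   frame, or numeric vector).
#' @param mean_dx,sigma_dx Paths to precomputed OpenDX mean/sigma grids (in
#'   volts, or kT300/e with `rescale = TRUE`).
#' @param control_points Path to a control-point CSV, or a `control_points`
#'   tibble.
#' @param grid A [grid_spec()]; required for the trajectory entry point.
#'   Its center is re-set per frame to that frame's centroid (the centroid
#'   convention for superposable frames); pass `recenter = FALSE` to keep
#'   the configured center for all frames.
#' @param pme A [pme_params()].
#' @param inscription An [inscription_spec()]; the cavity ellipsoid is
#'   inscribed in the first aligned frame. Alternatively supply `ellipsoid`
#'   directly (required for grid/control-point entry points unless the CSV
#'   carries one).
#' @param ellipsoid An [ellipsoid()] to use instead of inscription.
#' @param sigma_max Fluctuation threshold in volts.
#' @param orders Polynomial orders to fit.
#' @param rescale Whether grids are in kT300/e and must be rescaled to
#'   volts (`TRUE` for the trajectory entry point).
#' @param recenter Per-frame grid re-centering at the frame centroid.
#' @param out_dir Output directory for artifacts; `NULL` writes nothing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(trajectory = NULL, charges = NULL,
                            mean_dx = NULL, sigma_dx = NULL,
                            control_points = NULL,
                            grid = NULL, pme = pme_params(),
                            inscription = inscription_spec(),
                            ellipsoid = NULL,
                            sigma_max = 0.5, orders = c(1, 2),
                            rescale = TRUE, recenter = TRUE,
                            out_dir = NULL) {
  entries <- c(
    trajectory = !is.null(trajectory),
    grids = !is.null(mean_dx) || !is.null(sigma_dx),
    control_points = !is.null(control_points)
  )
  if (sum(entries) != 1) {
    abort("exactly one entry point must be set: trajectory, mean_dx/sigma_dx, or control_points")
  }
  if (entries[["grids"]] && (is.null(mean_dx) || is.null(sigma_dx))) {
    abort("the grid entry point needs both mean_dx and sigma_dx")
  }
  for (p in c(trajectory, charges, mean_dx, sigma_dx, control_points)) {
    if (is.character(p) && !file.exists(p)) abort(sprintf("input file not found: '%s'", p))
  }
  structure(
    list(trajectory = trajectory, charges = charges, mean_dx = mean_dx,
         sigma_dx = sigma_dx, control_points = control_points, grid = grid,
         pme = pme, inscription = inscription, ellipsoid = ellipsoid,
         sigma_max = sigma_max, orders = orders, rescale = rescale,
         recenter = recenter, out_dir = out_dir,
         entry = names(entries)[entries]),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields mirror the [pipeline_config()] arguments; `grid`, `pme`
#' and `inscription` are nested maps (`counts`/`box`/`center`,
#' `ewald_beta`/`spline_order`/`kmax`, `dz_min`/`dz_max`/`dz_step`/
#' `shrink_margin`/`half`), and `ellipsoid` a map with `center`/`radii`.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- if (!is.null(y$grid)) {
    grid_spec(unlist(y$grid$counts), unlist(y$grid$box),
              center = unlist(y$grid$center %||% c(0, 0, 0)))
  }
  pme <- if (!is.null(y$pme)) {
    pme_params(y$pme$ewald_beta %||% 0.25, y$pme$spline_order %||% 4,
               y$pme$kmax %||% 20)
  } else {
    pme_params()
  }
  insc <- if (!is.null(y$inscription)) {
    inscription_spec(
      dz_scan = seq(y$inscription$dz_min %||% -6, y$inscription$dz_max %||% 6,
                    by = y$inscription$dz_step %||% 1),
      shrink_margin = y$inscription$shrink_margin %||% 1,
      half = y$inscription$half %||% "upper"
    )
  } else {
    inscription_spec()
  }
  ell <- if (!is.null(y$ellipsoid)) {
    ellipsoid(unlist(y$ellipsoid$center), unlist(y$ellipsoid$radii))
  }
  pipeline_config(
    trajectory = y$trajectory, charges = y$charges,
    mean_dx = y$mean_dx, sigma_dx = y$sigma_dx,
    control_points = y$control_points,
    grid = grid, pme = pme, inscription = insc, ellipsoid = ell,
    sigma_max = y$sigma_max %||% 0.5,
    orders = unlist(y$orders %||% c(1, 2)),
    rescale = y$rescale %||% TRUE,
    recenter = y$recenter %||% TRUE,
    out_dir = y$out_dir
  )
}

#' Run the cavity-field pipeline
#'
#' Executes the stages downstream of the configured entry point:
#' trajectory alignment, per-frame reciprocal-space potential grids,
#' mean/sigma accumulation and volt rescaling; cavity ellipsoid
#' inscription; control-point selection; polynomial fits and the derived
#' field. When `out_dir` is set, artifacts are written (`mean.dx`,
#' `sigma.dx`, `ellipsoid.json`, `points.csv`, `model_order<k>.json`,
#' `report.json`) with numeric values printed at 6 significant digits.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `run_report` list: counts (`n_frames`, `n_inside`, `n_kept`,
#'   `percent_removed`), the `ellipsoid`, per-order `models` (fits), the
#'   constant `field` (V/Å and V/nm) when order 1 was fitted, `keyword`,
#'   per-stage `timings` (s), and the `entry` used. The fitted objects and
#'   control points ride along in `objects`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  clock <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(code), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  stats <- NULL
  ell <- config$ellipsoid
  points <- NULL
  n_frames <- NA_integer_

  if (config$entry == "trajectory") {
    traj <- clock("read", {
      if (inherits(config$trajectory, "charge_trajectory")) {
        config$trajectory
      } else {
        q <- config$charges
        if (is.character(q)) q <- read_pqr(q)
        read_trajectory(config$trajectory, charges = q)
      }
    })
    n_frames <- length(traj)
    if (is.null(config$grid)) abort("the trajectory entry point needs a grid spec")
    say("aligning %d frames", n_frames)
    traj <- clock("align", align_to_reference(traj, 1))
    say("computing reciprocal-space potential grids")
    stats <- clock("potential", {
      grids <- lapply(seq_len(n_frames), function(i) {
        f <- traj[[i]]
        spec_i <- if (config$recenter) {
          grid_spec(config$grid$counts, config$grid$box, center = frame_center(f))
        } else {
          config$grid
        }
        say("  frame %d/%d", i, n_frames)
        pme_reciprocal_grid(f, spec_i, config$pme)
      })
      accumulate_stats(grids, allow_center_drift = config$recenter)
    })
    if (config$rescale) stats <- rescale_to_volts(stats)
    if (is.null(ell)) {
      say("inscribing cavity ellipsoid")
      ell <- clock("ellipsoid", inscribe_ellipsoid(traj[[1]], config$inscription))
    }
  } else if (config$entry == "grids") {
    stats <- clock("read", {
      m <- read_grid_dx(config$mean_dx)
      s <- read_grid_dx(config$sigma_dx)
      if (!spec_equal(m$spec, s$spec)) abort("mean and sigma grids disagree in geometry")
      grid_stats(m$spec, m$values, s$values, n_frames = 1, units = m$units)
    })
    if (stats$units != "volt") stats <- rescale_to_volts(stats)
    if (is.null(ell)) abort("the grid entry point needs an ellipsoid")
  } else {
    points <- clock("read", {
      if (is.character(config$control_points)) {
        read_control_points(config$control_points)
      } else {
        config$control_points
      }
    })
    if (is.null(ell)) ell <- attr(points, "ellipsoid")
  }

  if (is.null(points)) {
    say("selecting control points")
    points <- clock("select", select_control_points(stats, ell, config$sigma_max))
  }
  n_inside <- attr(points, "n_inside") %||% NA_integer_
  n_kept <- attr(points, "n_kept") %||% nrow(points)

  say("fitting polynomial models")
  models <- clock("fit", {
    fits <- lapply(config$orders, function(k) fit_potential(points, order = k))
    names(fits) <- paste0("order", config$orders)
    fits
  })

  field <- NULL
  keyword <- NULL
  if ("order1" %in% names(models)) {
    fv <- field_of(models$order1)
    field <- list(
      volts_per_angstrom = c(ex = fv$ex, ey = fv$ey, ez = fv$ez),
      volts_per_nm = 10 * c(ex = fv$ex, ey = fv$ey, ez = fv$ez)
    )
    keyword <- export_field_keyword(fv, axis = "z")
  }

  report <- structure(
    list(
      entry = config$entry,
      n_frames = n_frames,
      n_inside = n_inside,
      n_kept = n_kept,
      percent_removed = if (is.na(n_inside)) NA_real_ else percent_removed(n_inside, n_kept),
      ellipsoid = list(center = ell$center, radii = ell$radii,
                       dz_best = attr(ell, "dz_best")),
      models = lapply(models, function(m) {
        list(order = m$order, coefficients = setNames(m$terms$estimate, m$terms$term),
             r_squared = m$r_squared)
      }),
      field = field,
      keyword = keyword,
      timings = timings,
      versions = list(
        cavityfield = as.character(utils::packageVersion("cavityfield")),
        r = paste(R.version$major, R.version$minor, sep = ".")
      )
    ),
    class = "run_report"
  )
  report$objects <- list(stats = stats, ellipsoid = ell, points = points,
                         models = models)
  if (!is.null(config$out_dir)) write_artifacts(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  entry: %s\n", x$entry))
  if (!is.na(x$n_inside)) {
    cat(sprintf("  control points: %d kept of %d inside (%.1f%% removed)\n",
                x$n_kept, x$n_inside, x$percent_removed))
  }
  for (m in x$models) {
    cat(sprintf("  order-%d fit: R^2 = %.4f\n", m$order, m$r_squared))
  }
  if (!is.null(x$keyword)) cat(sprintf("  %s\n", x$keyword))
  invisible(x)
}

write_artifacts <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- report$objects
  if (!is.null(obj$stats)) {
    write_grid_dx(obj$stats, file.path(out_dir, "mean.dx"), component = "mean")
    write_grid_dx(obj$stats, file.path(out_dir, "sigma.dx"), component = "sigma")
  }
  ell <- obj$ellipsoid
  jsonlite::write_json(
    list(center = signif(ell$center, 6), radii = signif(ell$radii, 6),
         dz_best = attr(ell, "dz_best")),
    file.path(out_dir, "ellipsoid.json"), auto_unbox = TRUE, digits = NA
  )
  write_control_points(obj$points, file.path(out_dir, "points.csv"))
  for (nm in names(obj$models)) {
    m <- obj$models[[nm]]
    jsonlite::write_json(
      list(order = m$order,
           terms = lapply(seq_len(nrow(m$terms)), function(i) {
             t <- m$terms[i, ]
             list(term = t$term, exponents = c(t$a, t$b, t$c),
                  coefficient = signif(t$estimate, 6))
           }),
           r_squared = signif(m$r_squared, 6),
           validity_region = if (!is.null(m$validity_region)) {
             list(center = signif(m$validity_region$center, 6),
                  radii = signif(m$validity_region$radii, 6))
           }),
      file.path(out_dir, paste0("model_", nm, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  clean <- report[c("entry", "n_frames", "n_inside", "n_kept", "percent_removed",
                    "ellipsoid", "models", "field", "keyword", "timings", "versions")]
  clean$percent_removed <- signif(clean$percent_removed, 6)
  clean$models <- lapply(clean$models, function(m) {
    m$coefficients <- signif(m$coefficients, 6)
    m$r_squared <- signif(m$r_squared, 6)
    m
  })
  if (!is.null(clean$field)) clean$field <- lapply(clean$field, signif, 6)
  clean$timings <- NULL  # timings vary run to run; keep artifacts diffable
  jsonlite::write_json(clean, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks the presence and types of the required report fields and the
#' internal count identity `percent_removed = 100 (n_inside - n_kept) /
#' n_inside`. The machine-readable field list ships at
#' `system.file("schema/report-schema.json", package = "cavityfield")`.
#'
#' @param report A `run_report` or a list parsed from `report.json`.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  required <- c("entry", "n_inside", "n_kept", "percent_removed",
                "ellipsoid", "models")
  for (f in required) {
    if (is.null(report[[f]])) abort(sprintf("report is missing field '%s'", f))
  }
  if (!is.na(report$n_inside)) {
    expect <- 100 * (report$n_inside - report$n_kept) / report$n_inside
    if (abs(expect - report$percent_removed) > 1e-6 + 1e-4 * abs(expect)) {
      abort("percent_removed does not match the count identity")
    }
  }
  for (m in report$models) {
    if (is.null(m$order) || is.null(m$r_squared)) {
      abort("each model entry needs 'order' and 'r_squared'")
    }
    if (m$r_squared > 1) abort("r_squared exceeds 1")
  }
  invisible(TRUE)
}
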