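#' Plane cut of a scalar grid
#'
#' Extracts the yz plane nearest a given x position (or any axis-normal
#' plane) and draws it as a raster, optionally with the cavity ellipsoid's
#' intersection curve — the standard way of eyeballing the potential or
#' sigma structure through the cavity.
#'
#' @param grid A [potential_grid()] or [grid_stats()].
#' @param at Plane position along the normal axis (Å).
#' @param normal Axis normal to the plane: "x", "y" or "z".
#' @param component For `grid_stats`: `"mean"` or `"sigma"`.
#' @param ellipsoid Optional [ellipsoid()] whose intersection with the
#'   plane is overlaid.
#' @return A ggplot object.
#' @export
plot_plane_cut <- function(grid, at, normal = c("x", "y", "z"),
                           component = c("mean", "sigma"), ellipsoid = NULL) {
  normal <- match.arg(normal)
  component <- match.arg(component)
  if (inherits(grid, "grid_stats")) {
    values <- grid[[component]]
    spec <- grid$spec
    lab <- if (component == "mean") "phi (V)" else "sigma (V)"
  } else {
    values <- grid$values
    spec <- grid$spec
    lab <- sprintf("phi (%s)", grid$units)
  }
  ax <- grid_axes(spec)
  d <- match(normal, c("x", "y", "z"))
  idx <- which.min(abs(ax[[normal]] - at))
  keep <- setdiff(1:3, d)
  slice <- switch(normal,
                  x = values[idx, , ],
                  y = values[, idx, ],
                  z = values[, , idx])
  axes_keep <- ax[keep]
  df <- tidyr::expand_grid(
    v2 = axes_keep[[2]], v1 = axes_keep[[1]]
  )[, c("v1", "v2")]
  df$value <- as.vector(slice)
  names(df)[1:2] <- names(axes_keep)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[names(axes_keep)[1]]],
                                        .data[[names(axes_keep)[2]]],
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s = %.2f Å plane", normal, ax[[normal]][idx]),
      x = paste0(names(axes_keep)[1], " (Å)"), y = paste0(names(axes_keep)[2], " (Å)")
    )
  if (!is.null(ellipsoid)) {
    cn <- ellipsoid$center[d]
    rn <- ellipsoid$radii[d]
    t <- 1 - ((ax[[normal]][idx] - cn) / rn)^2
    if (t > 0) {
      s <- sqrt(t)
      theta <- seq(0, 2 * pi, length.out = 200)
      ring <- tibble(
        a = ellipsoid$center[keep[1]] + s * ellipsoid$radii[keep[1]] * cos(theta),
        b = ellipsoid$center[keep[2]] + s * ellipsoid$radii[keep[2]] * sin(theta)
      )
      names(ring) <- names(axes_keep)
      p <- p + ggplot2::geom_path(
        data = ring,
        ggplot2::aes(.data[[names(axes_keep)[1]]], .data[[names(axes_keep)[2]]]),
        inherit.aes = FALSE, color = "white", linewidth = 0.4
      )
    }
  }
  p
}

#' Histogram and CDFs of the in-cavity sigma distribution
#'
#' Density-normalized histogram of sigma with the empirical CDF and the
#' fitted normal CDF overlaid, plus the threshold line.
#'
#' @param object A [sigma_distribution()].
#' @param threshold Threshold to mark (V); `NULL` for none.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sigma_distribution <- function(object, threshold = 0.5, ...) {
  bins <- object$bins
  grid_x <- seq(min(bins$lower), max(bins$upper), length.out = 200)
  cdfs <- tibble(
    x = rep(grid_x, 2),
    y = c(object$ecdf(grid_x),
          pnorm(grid_x, object$normal$mean, object$normal$sd)),
    which = rep(c("empirical CDF", "normal CDF"), each = length(grid_x))
  )
  scale <- max(bins$density)
  p <- ggplot2::ggplot(bins) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                                    ymin = 0, ymax = .data$density),
                       fill = "steelblue", alpha = 0.6) +
    ggplot2::geom_line(data = cdfs,
                       ggplot2::aes(.data$x, .data$y * scale,
                                    color = .data$which, linetype = .data$which)) +
    ggplot2::scale_y_continuous(
      name = "density",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "CDF")
    ) +
    ggplot2::labs(x = "sigma (V)", color = NULL, linetype = NULL)
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}

#' Relative field components per control point
#'
#' Scatter of |Ex|/|E|, |Ey|/|E| and -Ez/|E| against the control-point
#' index, making the axial dominance of the field visible at a glance.
#'
#' @param components Output of [relative_components()].
#' @return A ggplot object.
#' @export
plot_field_components <- function(components) {
  df <- dplyr::mutate(as_tibble(components), index = dplyr::row_number())
  long <- tidyr::pivot_longer(
    df[!df$degenerate, c("index", "rel_ex", "rel_ey", "rel_ez_down")],
    cols = -"index", names_to = "component", values_to = "value"
  )
  labels <- c(rel_ex = "|Ex|/|E|", rel_ey = "|Ey|/|E|", rel_ez_down = "-Ez/|E|")
  ggplot2::ggplot(long, ggplot2::aes(.data$index, .data$value,
                                     color = labels[.data$component])) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::labs(x = "control point index", y = "relative component", color = NULL)
}
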