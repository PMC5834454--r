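#' Plot a density grid as a z-averaged top view
#'
#' @param object A `density_grid`.
#' @param zmax Axial averaging half-window, nm.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_grid <- function(object, zmax = 25, ...) {
  zt <- z_average(object, zmax = zmax)
  cx <- .cell_centers(object, 1)
  cy <- .cell_centers(object, 2)
  df <- tidyr::expand_grid(y = cy, x = cx)[, c("x", "y")]
  df$rho <- as.vector(zt$xy)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$rho)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "rho (mg/ml)") +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = sprintf("z-averaged protein density (|z| <= %g nm)",
                                  zmax))
}

#' Plot a circumferentially averaged density map (side view)
#'
#' @param object A `cyl_rz`.
#' @param r_max Radial display limit, nm.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyl_rz <- function(object, r_max = max(object$r), ...) {
  keep <- object$r <= r_max
  df <- tidyr::expand_grid(z = object$z, r = object$r[keep])[, c("r", "z")]
  df$rho <- as.vector(object$rho[keep, ])
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$z, fill = .data$rho)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "rho (mg/ml)") +
    ggplot2::labs(x = "r (nm)", y = "z (nm)",
                  title = "circumferentially averaged density rho(r, z)")
}

#' Plot a current trace with detected docking events
#'
#' @param object A `trace_record`.
#' @param events Optional event tibble from [extract_docking_events()].
#' @param max_points Downsampling cap on plotted samples.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trace_record <- function(object, events = NULL, max_points = 20000,
                                  ...) {
  idx <- if (nrow(object) > max_points) {
    round(seq(1, nrow(object), length.out = max_points))
  } else seq_len(nrow(object))
  p <- ggplot2::ggplot(object[idx, ],
                       ggplot2::aes(.data$time, .data$current)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "current (nA)")
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = events, inherit.aes = FALSE, alpha = 0.2, fill = "orange",
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf))
  }
  p
}

#' Plot a photobleaching trace with its fitted staircase
#'
#' @param object A `bleach_counts` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bleach_counts <- function(object, ...) {
  n <- length(object$trace)
  tt <- (seq_len(n) - 1) / object$frame_rate
  bounds <- c(0, object$changepoints, n)
  fit <- rep(object$levels, times = diff(bounds))
  df <- tibble(time = tt, intensity = object$trace, fit = fit)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$intensity)) +
    ggplot2::geom_line(colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_step(ggplot2::aes(y = .data$fit), colour = "red") +
    ggplot2::labs(x = "time (s)", y = "intensity (a.u.)",
                  title = sprintf("%d bleaching steps", object$n_steps))
}

#' Plot radial density profiles
#'
#' @param profiles A single profile tibble from [radial_profile()] or a
#'   named list of them.
#' @return A ggplot object.
#' @export
plot_radial_profile <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- list(profile = profiles)
  df <- purrr::imap_dfr(profiles, function(p, nm) {
    tibble(variant = nm, r = p$r, rho = p$rho)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$rho,
                                   colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (nm)", y = "rho (mg/ml)")
}
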