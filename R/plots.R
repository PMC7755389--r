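#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot the dimensionless pump and system characteristics
#'
#' The pump line `P^ = 1 - Q^` with system lines `P^ = R^ Q^` and their
#' operating points, for the gasket (R^ ~ 0.1), gasket-less syconoid
#' (R^ ~ 1) and impaired (R^ ~ 100) regimes.
#'
#' @param object Output of [characteristic_curves()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pump_system_curves <- function(object, ...) {
  curves <- object$curves
  ops <- object$operating_points
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = dplyr::filter(curves, .data$curve == "pump"),
      ggplot2::aes(.data$q_hat, .data$p_hat), linewidth = 1) +
    ggplot2::geom_line(
      data = dplyr::filter(curves, .data$curve == "system"),
      ggplot2::aes(.data$q_hat, .data$p_hat,
                   group = .data$r_hat, linetype = factor(.data$r_hat))) +
    ggplot2::geom_point(
      data = ops, ggplot2::aes(.data$q_hat_op, .data$p_hat_op), size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = expression(hat(Q)), y = expression(hat(P)),
                  linetype = expression(R[ost] / C[pump])) +
    ggplot2::theme_minimal()
}

#' Plot the time-averaged velocity field on a mid-plane slice
#'
#' Speed map with the solid/porous structures overlaid, on the vertical
#' plane through the ostium centre — the view in which the backflow and the
#' stagnation zone (hydrodynamic gasket) above the ostium are visible.
#'
#' @param object A `chamber_flow`.
#' @param plane `"xy"` (through the beat plane) or `"zy"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chamber_flow <- function(object, plane = c("xy", "zy"), ...) {
  plane <- match.arg(plane)
  cell <- object$cell
  nx <- cell$nx; ny <- cell$ny; nz <- cell$nz
  ua <- array(object$u, dim = c(nx, ny, nz))
  va <- array(object$v, dim = c(nx, ny + 1, nz))
  wa <- array(object$w, dim = c(nx, ny, nz + 1))
  uc <- (ua + ua[c(2:nx, 1), , , drop = FALSE]) / 2
  vc <- (va[, 1:ny, , drop = FALSE] + va[, 2:(ny + 1), , drop = FALSE]) / 2
  wc <- (wa[, , 1:nz, drop = FALSE] + wa[, , 2:(nz + 1), drop = FALSE]) / 2
  if (plane == "xy") {
    kc <- which.min(abs(cell$z - cell$centre[["z"]]))
    df <- tidyr::expand_grid(yi = seq_len(ny), xi = seq_len(nx))
    df <- dplyr::mutate(df,
      horiz = cell$x[.data$xi], vert = cell$y[.data$yi],
      vel_h = uc[cbind(.data$xi, .data$yi, kc)],
      vel_v = vc[cbind(.data$xi, .data$yi, kc)],
      label = cell$label[cbind(.data$xi, .data$yi, kc)])
  } else {
    ic <- which.min(abs(cell$x - cell$centre[["x"]]))
    df <- tidyr::expand_grid(yi = seq_len(ny), zi = seq_len(nz))
    df <- dplyr::mutate(df,
      horiz = cell$z[.data$zi], vert = cell$y[.data$yi],
      vel_h = wc[cbind(ic, .data$yi, .data$zi)],
      vel_v = vc[cbind(ic, .data$yi, .data$zi)],
      label = cell$label[cbind(ic, .data$yi, .data$zi)])
  }
  df$speed <- sqrt(df$vel_h^2 + df$vel_v^2)
  ggplot2::ggplot(df, ggplot2::aes(.data$horiz, .data$vert)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$speed)) +
    ggplot2::geom_tile(
      data = dplyr::filter(df, .data$label > 0),
      fill = "grey30", alpha = 0.8) +
    ggplot2::scale_fill_viridis_c(name = "speed (um/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = sprintf("%s (um)", substr(plane, 1, 1)), y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Box plot of retention efficiencies per prey class
#'
#' @param object A `retention_summary`.
#' @param ... Unused.
#' @return A ggplot drawn from the summary statistics (median, quartile box,
#'   1.5 x IQR whiskers, outlier points).
#' @export
autoplot.retention_summary <- function(object, ...) {
  outl <- tidyr::unnest(object[, c("class", "outliers")],
                        "outliers")
  ggplot2::ggplot(object, ggplot2::aes(x = toupper(.data$class))) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_lo, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_hi),
      stat = "identity", width = 0.5) +
    ggplot2::geom_point(data = outl,
                        ggplot2::aes(y = .data$outliers), shape = 1) +
    ggplot2::labs(x = NULL, y = "Retention efficiency (%)") +
    ggplot2::theme_minimal()
}

#' @export
tidy.pump_characteristic <- function(x, ...) {
  tibble::tibble(
    term = c("q_max", "p_max", "c_pump"),
    estimate = c(x$q_max, x$p_max, x$c_pump),
    unit = c("um^3/s", "Pa", "Pa s um^-3")
  )
}

#' @export
glance.pump_characteristic <- function(x, ...) {
  tibble::tibble(
    q_max = x$q_max, p_max = x$p_max, c_pump = x$c_pump,
    c_pump_upa = 1e6 * x$c_pump,
    r_squared = x$r_squared %||% NA_real_,
    n_samples = x$n_samples %||% NA_integer_
  )
}

#' @export
tidy.grid_convergence <- function(x, ...) x$table

#' @export
glance.retention_summary <- function(x, ...) {
  tibble::as_tibble(x[, c("class", "n", "median", "mean", "se", "sd")])
}
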