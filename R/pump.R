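#' Hagen-Poiseuille resistance of a circular canal
#'
#' Resistance of a straight circular tube in creeping flow,
#' `R = 128 mu L / (pi D^4)`, used for the ostium/canal system curve.
#'
#' @param diameter Tube diameter (um).
#' @param length Tube length (um); zero is allowed (a perforation with no
#'   tube has no Poiseuille resistance).
#' @param mu Dynamic viscosity (Pa s). Default `1e-3` (seawater-like).
#' @return Resistance in Pa s um^-3. Multiply by `1e6` for uPa s um^-3.
#' @examples
#' poiseuille_resistance(7, 3) * 1e6  # ~51 uPa s um^-3, reference ostium
#' @export
poiseuille_resistance <- function(diameter, length, mu = 1e-3) {
  if (any(diameter <= 0)) {
    stop("invalid geometry: tube diameter must be positive", call. = FALSE)
  }
  if (any(length < 0)) {
    stop("invalid geometry: tube length must be non-negative", call. = FALSE)
  }
  128 * mu * length / (pi * diameter^4)
}

#' Pump characteristic of a basic pumping unit
#'
#' A low-Reynolds-number pump is linear: delivered pressure falls from
#' `P_max` (at zero flow) to zero (at `Q_max`), i.e. `P/P_max = 1 - Q/Q_max`.
#'
#' @param q_max Maximum pumping rate at zero load (um^3/s).
#' @param p_max Maximum pressure at zero net flow (Pa).
#' @return A `pump_characteristic` object with fields `q_max`, `p_max` and
#'   `c_pump = p_max / q_max` (Pa s um^-3).
#' @seealso [characterize_pump()] to fit one from simulated samples,
#'   [operating_point()] to intersect it with a system curve.
#' @export
pump_characteristic <- function(q_max, p_max) {
  stopifnot(is.numeric(q_max), is.numeric(p_max), length(q_max) == 1,
            length(p_max) == 1)
  if (q_max <= 0 || p_max <= 0) {
    stop("q_max and p_max must be positive", call. = FALSE)
  }
  structure(
    list(q_max = q_max, p_max = p_max, c_pump = p_max / q_max),
    class = "pump_characteristic"
  )
}

#' @export
print.pump_characteristic <- function(x, ...) {
  cat("Linear pump characteristic P/P_max = 1 - Q/Q_max\n")
  cat(sprintf("  Q_max : %.4g um^3/s\n", x$q_max))
  cat(sprintf("  P_max : %.4g Pa\n", x$p_max))
  cat(sprintf("  C_pump: %.4g uPa s um^-3 (P_max/Q_max)\n", 1e6 * x$c_pump))
  if (!is.null(x$r_squared)) {
    cat(sprintf("  fit R2: %.6f over %d back-pressure samples\n",
                x$r_squared, x$n_samples))
  }
  invisible(x)
}

#' System curve of the canal resistance
#'
#' @param r_ost Canal (ostium) resistance in Pa s um^-3, e.g. from
#'   [poiseuille_resistance()].
#' @param pump A [pump_characteristic()]; its `c_pump` normalises the slope.
#' @return A `system_curve` object with `r_ost` and the dimensionless slope
#'   `r_hat = r_ost / c_pump` of the normalised system line `P^ = r_hat Q^`.
#' @export
system_curve <- function(r_ost, pump) {
  stopifnot(inherits(pump, "pump_characteristic"))
  if (r_ost < 0) stop("r_ost must be non-negative", call. = FALSE)
  structure(
    list(r_ost = r_ost, c_pump = pump$c_pump, r_hat = r_ost / pump$c_pump),
    class = "system_curve"
  )
}

#' Operating point of a pumping unit on its canal system
#'
#' Intersects the normalised pump line `P^ = 1 - Q^` with the system line
#' `P^ = R^ Q^`, giving `Q^ = 1/(1 + R^)` and `P^ = R^/(1 + R^)`. A unit with
#' `R^ = 1` (typical gasket-less syconoid ostium) delivers half its maximum
#' capacity; `R^ ~ 0.1` (leucon with physical gasket) delivers nearly all of
#' it; `R^ ~ 100` is effectively stalled.
#'
#' @param pump A [pump_characteristic()].
#' @param system A [system_curve()], or a bare non-negative number taken as
#'   the dimensionless resistance ratio `R^`.
#' @return A one-row tibble: `r_hat`, `q_hat_op`, `p_hat_op`, and the
#'   dimensional `q_op` (um^3/s) and `p_op` (Pa).
#' @export
operating_point <- function(pump, system) {
  stopifnot(inherits(pump, "pump_characteristic"))
  r_hat <- if (inherits(system, "system_curve")) system$r_hat else {
    stopifnot(is.numeric(system), length(system) == 1, system >= 0)
    as.numeric(system)
  }
  q_hat <- 1 / (1 + r_hat)
  p_hat <- r_hat * q_hat
  tibble::tibble(
    r_hat = r_hat,
    q_hat_op = q_hat,
    p_hat_op = p_hat,
    q_op = q_hat * pump$q_max,
    p_op = p_hat * pump$p_max
  )
}

#' Fit a pump characteristic to simulated back-pressure samples
#'
#' Takes time-averaged (back-pressure, flow) samples of the basic pumping
#' unit — the zero-length-ostium cell with its 24 choanocytes — and fits the
#' linear characteristic by least squares. `Q_max` is the zero-pressure
#' intercept and `P_max` the zero-flow intercept.
#'
#' @param samples Data frame with columns `dp` (imposed adverse back-pressure,
#'   Pa) and `q` (time-averaged ostium flow, um^3/s); at least two distinct
#'   back-pressures.
#' @param min_r_squared Linearity guard: the fit's R^2 must exceed this when
#'   there are more than two samples (creeping flow is linear, so anything
#'   less signals a solver problem). Default 0.999.
#' @return A `pump_characteristic` with `r_squared` and `n_samples` attached.
#' @export
characterize_pump <- function(samples, min_r_squared = 0.999) {
  samples <- tibble::as_tibble(samples)
  if (!all(c("dp", "q") %in% names(samples))) {
    stop("samples must have columns `dp` and `q`", call. = FALSE)
  }
  if (nrow(samples) < 2 || length(unique(samples$dp)) < 2) {
    stop("need samples at >= 2 distinct back-pressures", call. = FALSE)
  }
  fit <- stats::lm(q ~ dp, data = samples)
  slope <- stats::coef(fit)[["dp"]]
  q0 <- stats::coef(fit)[["(Intercept)"]]
  if (slope >= 0 || q0 <= 0) {
    stop("degenerate samples: flow must decrease with back-pressure from a positive Q_max",
         call. = FALSE)
  }
  # a near-perfect fit is the expected outcome in creeping flow; summary()
  # warns about it, which is noise here
  r2 <- if (nrow(samples) > 2) {
    suppressWarnings(summary(fit)$r.squared)
  } else 1
  if (r2 < min_r_squared) {
    stop(sprintf("pump samples are not linear (R^2 = %.5f): check solver convergence", r2),
         call. = FALSE)
  }
  pc <- pump_characteristic(q_max = q0, p_max = -q0 / slope)
  pc$r_squared <- r2
  pc$n_samples <- nrow(samples)
  pc
}

#' Round a pump resistance the way it is conventionally reported
#'
#' Reports `C_pump` in uPa s um^-3 rounded to the nearest ten.
#'
#' @param c_pump Resistance in Pa s um^-3 (as stored on a
#'   [pump_characteristic()]).
#' @return Rounded value in uPa s um^-3.
#' @export
report_c_pump <- function(c_pump) {
  round(c_pump * 1e6 / 10) * 10
}

#' Dimensionless pump and system characteristic curves
#'
#' Tabulates the pump line `P^ = 1 - Q^` and system lines `P^ = R^ Q^` for a
#' set of resistance ratios, with their operating-point intersections, for
#' plotting.
#'
#' @param r_hat Dimensionless resistance ratios `R_ost/C_pump`; defaults to
#'   the three regimes: 0.1 (leucon unit with physical gasket), 1 (gasket-less
#'   syconoid unit), 100 (gasket-less unit on a narrow leucon-like canal
#'   system, impaired).
#' @param n Points per curve.
#' @return A list of tibbles: `curves` (columns `curve`, `r_hat`, `q_hat`,
#'   `p_hat`) and `operating_points`.
#' @export
characteristic_curves <- function(r_hat = c(0.1, 1, 100), n = 101) {
  stopifnot(all(r_hat >= 0))
  q <- seq(0, 1, length.out = n)
  pump_line <- tibble::tibble(curve = "pump", r_hat = NA_real_,
                              q_hat = q, p_hat = 1 - q)
  sys_lines <- purrr::map_dfr(r_hat, function(r) {
    qmax <- min(1, 1 / max(r, 1e-12))  # clip to the unit box
    qs <- seq(0, qmax, length.out = n)
    tibble::tibble(curve = "system", r_hat = r, q_hat = qs, p_hat = r * qs)
  })
  ops <- purrr::map_dfr(r_hat, function(r) {
    q <- 1 / (1 + r)
    tibble::tibble(r_hat = r, q_hat_op = q, p_hat_op = r * q)
  })
  structure(list(curves = dplyr::bind_rows(pump_line, sys_lines),
                 operating_points = ops),
            class = "pump_system_curves")
}
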