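#' Travelling-wave beat kinematics of the vaned flagella
#'
#' The beat is a base-to-tip travelling sine wave with a saturating Gaussian
#' amplitude envelope,
#' `d(s, t) = a (1 - exp(-(s/delta)^2)) sin(2 pi (s/lambda - f t) + phase)`,
#' applied transverse to the collar axis. The base case
#' (`a = 1, delta = 1` um) keeps the amplitude near 1 um along most of the
#' flagellum so the wave fits inside the collar; the increased-amplitude
#' modulation (`a = 5, delta = 22` um) grows to a maximum of 2 um at the tip.
#'
#' @param lambda Wavelength (um).
#' @param a Amplitude scale (um).
#' @param delta Envelope length scale (um).
#' @param f Beat frequency (Hz).
#' @param vane_width Vane width (um); scalar, or length-2
#'   `c(confined, unconfined)` for a piecewise vane that is wider on the
#'   unconfined part of the flagellum (above the collar) than inside it.
#' @param l_f Flagellum length (um). The default 15.7 um makes the
#'   increased-amplitude envelope peak at exactly 2 um at the tip.
#' @param phase Per-flagellum phase offsets (radians); recycled to the
#'   number of flagella. Default: all beating in phase.
#' @param beat_azimuth Per-flagellum beat-plane azimuth (radians) about the
#'   collar axis; recycled. Default: a common plane.
#' @param presence `"full"`, `"unconfined"` (sheet exists only above the
#'   collar tip) or `"confined"` (only inside the collar) — the two
#'   hypothetical decompositions of the pumping mechanism.
#' @return A `beat_kinematics` object.
#' @export
beat_kinematics <- function(lambda = 5.0, a = 1.0, delta = 1.0, f = 30,
                            vane_width = 0.7, l_f = 15.7,
                            phase = 0, beat_azimuth = 0,
                            presence = c("full", "unconfined", "confined")) {
  presence <- match.arg(presence)
  stopifnot(lambda > 0, a > 0, delta > 0, f > 0, l_f > 0,
            all(vane_width >= 0), length(vane_width) %in% c(1, 2))
  structure(
    list(lambda = lambda, a = a, delta = delta, f = f,
         vane_width = vane_width, l_f = l_f,
         phase = phase, beat_azimuth = beat_azimuth,
         presence = presence, period = 1 / f),
    class = "beat_kinematics"
  )
}

#' @export
print.beat_kinematics <- function(x, ...) {
  cat(sprintf(
    "Flagellar beat: lambda = %g um, a = %g um, delta = %g um, f = %g Hz\n",
    x$lambda, x$a, x$delta, x$f))
  vw <- if (length(x$vane_width) == 2) {
    sprintf("%g um confined / %g um unconfined", x$vane_width[1], x$vane_width[2])
  } else sprintf("%g um", x$vane_width)
  cat(sprintf("  vane %s, L_f = %g um, presence: %s\n", vw, x$l_f, x$presence))
  invisible(x)
}

#' Transverse displacement of the beat waveform
#'
#' @param s Arclength from the flagellar base (um), in `[0, l_f]`.
#' @param t Time (s).
#' @param k A [beat_kinematics()].
#' @param phase Phase offset (radians) of this flagellum.
#' @return Transverse displacement (um), vectorised over `s` and `t`.
#' @examples
#' waveform(0, 0.01, beat_kinematics())        # clamped base: 0
#' waveform(15.7, 0, beat_kinematics(a = 5, delta = 22))
#' @export
waveform <- function(s, t, k = beat_kinematics(), phase = 0) {
  if (any(s < -1e-9) || any(s > k$l_f + 1e-9)) {
    stop("arclength s outside [0, l_f]", call. = FALSE)
  }
  envelope(s, k) * sin(2 * pi * (s / k$lambda - k$f * t) + phase)
}

envelope <- function(s, k) {
  k$a * (1 - exp(-(s / k$delta)^2))
}

# Axial extent H(t) such that the centreline arclength from base to tip is
# l_f: the waveform is written in the axial coordinate, and the sheet is
# compressed axially each phase to keep the centreline inextensible.
axial_extent <- function(t, k, phase = 0) {
  arclen <- function(H) {
    zeta <- seq(0, H, length.out = 201)
    integrand <- sqrt(1 + waveform_slope(zeta, t, k, phase)^2)
    sum((integrand[-1] + integrand[-201]) / 2) * H / 200
  }
  lo <- k$l_f / 3; hi <- k$l_f
  stats::uniroot(function(H) arclen(H) - k$l_f, c(lo, hi), tol = 1e-6)$root
}

waveform_slope <- function(zeta, t, k, phase = 0) {
  arg <- 2 * pi * (zeta / k$lambda - k$f * t) + phase
  denv <- k$a * exp(-(zeta / k$delta)^2) * 2 * zeta / k$delta^2
  denv * sin(arg) + envelope(zeta, k) * cos(arg) * 2 * pi / k$lambda
}

# Marker positions at fixed arclengths s: invert the arclength integral to
# axial coordinates, then evaluate the transverse displacement there.
sheet_markers <- function(s, t, k, phase = 0, n_quad = 400) {
  H <- axial_extent(t, k, phase)
  zq <- seq(0, H, length.out = n_quad + 1)
  dz <- H / n_quad
  integrand <- sqrt(1 + waveform_slope(zq, t, k, phase)^2)
  cums <- c(0, cumsum((integrand[-1] + integrand[-(n_quad + 1)]) / 2 * dz))
  zeta <- stats::approx(cums, zq, xout = pmin(s, max(cums)), rule = 2)$y
  d <- envelope(zeta, k) * sin(2 * pi * (zeta / k$lambda - k$f * t) + phase)
  list(axial = zeta, transverse = d, H = H)
}

#' Sheet state of every flagellum at one beat phase
#'
#' Positions and velocities of each flagellar sheet: the centreline (markers
#' at fixed arclength, so the sheet is inextensible to within the quadrature
#' tolerance), the local vane half-width, and the beat-plane direction of
#' each flagellum. Velocities are time derivatives of the marker positions
#' at fixed arclength, evaluated by Richardson-extrapolated central
#' differencing of the (implicitly defined) marker map.
#'
#' @param t Time (s).
#' @param k A [beat_kinematics()].
#' @param geom A `chamber_geometry` (collar positions and heights).
#' @param n_markers Markers per flagellum.
#' @param base_height Height of the flagellar bases above the cell floor
#'   (um); defaults to the ostium length (top of the chamber wall).
#' @return A `sheet_state`: tibble with one row per marker per flagellum —
#'   `flagellum`, `s`, `x`, `y`, `z`, `vx`, `vy`, `vz`, `half_width`,
#'   plus the kinematics and phase as attributes.
#' @export
sheet_state <- function(t, k, geom, n_markers = 64,
                        base_height = geom$l_ost) {
  stopifnot(inherits(k, "beat_kinematics"), inherits(geom, "chamber_geometry"))
  collars <- collar_positions(geom)
  n_fl <- nrow(collars)
  phase <- rep_len(k$phase, n_fl)
  azim <- rep_len(k$beat_azimuth, n_fl)
  wall_top <- base_height
  s <- seq(0, k$l_f, length.out = n_markers)

  dt <- 1e-4 * k$period
  rows <- purrr::map_dfr(seq_len(n_fl), function(i) {
    m0 <- sheet_markers(s, t, k, phase[i])
    mp <- sheet_markers(s, t + dt, k, phase[i])
    mm <- sheet_markers(s, t - dt, k, phase[i])
    mp2 <- sheet_markers(s, t + 2 * dt, k, phase[i])
    mm2 <- sheet_markers(s, t - 2 * dt, k, phase[i])
    # 4th-order central difference at fixed arclength
    v_tr <- (8 * (mp$transverse - mm$transverse) -
               (mp2$transverse - mm2$transverse)) / (12 * dt)
    v_ax <- (8 * (mp$axial - mm$axial) - (mp2$axial - mm2$axial)) / (12 * dt)
    keep <- switch(k$presence,
      full = rep(TRUE, length(s)),
      unconfined = m0$axial > geom$l_col,
      confined = m0$axial <= geom$l_col
    )
    w <- vane_half_width(m0$axial, k, geom)
    tibble::tibble(
      flagellum = i,
      s = s[keep],
      x = collars$x[i] + m0$transverse[keep] * cos(azim[i]),
      y = wall_top + m0$axial[keep],
      z = collars$z[i] + m0$transverse[keep] * sin(azim[i]),
      vx = v_tr[keep] * cos(azim[i]),
      vy = v_ax[keep],
      vz = v_tr[keep] * sin(azim[i]),
      azimuth = azim[i],
      half_width = w[keep]
    )
  })
  structure(rows, class = c("sheet_state", class(rows)),
            t = t, kinematics = k)
}

vane_half_width <- function(axial, k, geom) {
  if (length(k$vane_width) == 2) {
    ifelse(axial <= geom$l_col, k$vane_width[1] / 2, k$vane_width[2] / 2)
  } else {
    rep_len(k$vane_width / 2, length(axial))
  }
}
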