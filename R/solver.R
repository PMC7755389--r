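#' Solver configuration
#'
#' Numerical parameters of the quasi-steady Stokes solver. Each beat phase is
#' solved as a steady creeping-flow problem (the Reynolds number of the
#' chamber flow is ~1e-3 and the oscillatory boundary layer at 30 Hz is far
#' thicker than the chamber, so the flow is quasi-static); the solver is an
#' artificial-compressibility pseudo-time iteration on a staggered Cartesian
#' grid with volume penalization for solids, a Brinkman drag term for the
#' porous collar shells, and direct forcing of the moving flagellar sheets.
#'
#' Two bundled profiles: `"test"` (h = 1.0 um, 8 phases) runs a full beat
#' cycle in seconds and is used throughout the test-suite; `"full"`
#' (h = 0.5 um, 8 phases) is the production profile used for the
#' quantitative results.
#'
#' @param h Grid spacing (um).
#' @param n_phases Beat phases per period (>= 4).
#' @param tol Convergence tolerance: pseudo-time momentum residual relative
#'   to the viscous force scale `mu U / h^2` of the fastest sheet.
#' @param max_iter Pseudo-time iteration cap per phase.
#' @param check_every Residual check interval.
#' @param safety Pseudo-time step safety factor (< 1).
#' @param alpha_pen Solid penalization coefficient (Pa s um^-2); default
#'   `NULL` picks `max(1e4 mu / h^2, 2e3 x max collar resistance)`.
#' @param alpha_sheet Sheet penalization coefficient (Pa s um^-2) dragging
#'   cut faces toward the sheet velocity; default `NULL` picks
#'   `400 mu / h^2` (residual sheet slip well under 1% of the beat speed
#'   while every face stays pressure-responsive, so the moving sheet cannot
#'   act as a volume source).
#' @param dp_in Uniform back-pressure imposed on the inlet face (Pa);
#'   positive values oppose the pump.
#' @param half_period Exploit the half-period mirror symmetry of an in-phase,
#'   common-plane beat (phase t + T/2 is the mirror image of phase t, so
#'   fluxes repeat); `NULL` decides automatically from the kinematics.
#' @param profile Shorthand: `"test"` or `"full"`; explicit arguments
#'   override the profile values.
#' @return A `solver_config` object.
#' @export
solver_config <- function(h = NULL, n_phases = NULL, tol = 3e-6,
                          max_iter = 100000L, check_every = 100L,
                          safety = 0.45, alpha_pen = NULL, alpha_sheet = NULL,
                          dp_in = 0, half_period = NULL,
                          profile = c("test", "full")) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    test = list(h = 1.0, n_phases = 8L),
    full = list(h = 0.5, n_phases = 8L)
  )
  h <- h %||% defaults$h
  n_phases <- as.integer(n_phases %||% defaults$n_phases)
  stopifnot(h > 0, n_phases >= 4, tol > 0, safety > 0, safety <= 1)
  structure(
    list(h = h, n_phases = n_phases, tol = tol,
         max_iter = as.integer(max_iter),
         check_every = as.integer(check_every), safety = safety,
         alpha_pen = alpha_pen, alpha_sheet = alpha_sheet,
         dp_in = dp_in, half_period = half_period,
         profile = profile),
    class = "solver_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_alpha_pen <- function(cell, config) {
  config$alpha_pen %||%
    max(1e4 * cell$mu / config$h^2,
        2e3 * max(cell$brinkman, cell$mem_u_coef, cell$mem_w_coef, 1e-12))
}

# Penalization drag fraction from the cell solidity: full cells get the full
# penalization coefficient; partly solid cells get a finite permeability-type
# drag C mu/h^2 * psi/(1-psi) so the effective no-slip plane of a wall cut
# through a cell falls on the true surface (C calibrated once against the
# Hagen-Poiseuille closed form, then validated on independent flows).
penal_partial_C <- 32
penal_fraction <- function(psi, h, mu, alpha_pen, C = penal_partial_C) {
  a_part <- C * mu / h^2 * psi / pmax(1 - psi, 1e-6)
  frac <- pmin(a_part / alpha_pen, 1)
  frac[psi >= 0.9999] <- 1
  frac
}

# Face forcing lists from the sheet states at time t. Markers along the
# centreline (arclength step ~ h/2) are swept across the vane width; every
# sample constrains its nearest u, v and w faces to the sheet's no-slip
# velocity. The sheet is impermeable, so cut faces are fully constrained;
# vane widths below the grid spacing are represented at one-face resolution
# (a documented limit of the discretisation).
sheet_forcing <- function(cell, kin, t, n_markers = NULL) {
  h <- cell$h
  n_markers <- n_markers %||% max(64L, as.integer(ceiling(2 * kin$l_f / h)) + 1L)
  st <- sheet_state(t, kin, cell$geom, n_markers = n_markers,
                    base_height = cell$wall_top)
  nx <- cell$nx; ny <- cell$ny; nz <- cell$nz
  dirx <- -sin(st$azimuth); dirz <- cos(st$azimuth)  # vane direction
  max_off <- max(st$half_width)
  n_off <- max(1L, as.integer(ceiling(2 * max_off / (h / 2))) + 1L)
  offs <- if (n_off == 1L) 0 else seq(-1, 1, length.out = n_off)
  px <- numeric(0); py <- numeric(0); pz <- numeric(0)
  vx <- numeric(0); vz <- numeric(0)
  for (o in offs) {
    px <- c(px, st$x + o * st$half_width * dirx)
    py <- c(py, st$y)
    pz <- c(pz, st$z + o * st$half_width * dirz)
    vx <- c(vx, st$vx); vz <- c(vz, st$vz)
  }
  keep <- py >= 0 & py < ny * h & pz >= 0 & pz < nz * h
  px <- px[keep]; py <- py[keep]; pz <- pz[keep]
  vx <- vx[keep]; vz <- vz[keep]
  ic <- floor(px / h) %% nx
  jc <- pmin(pmax(floor(py / h), 0), ny - 1)
  kc <- pmin(pmax(floor(pz / h), 0), nz - 1)
  # samples landing in solid or gasket cells are not forced (the flagellum
  # never touches walls); collar-membrane faces are excluded in the kernel
  lab <- cell$label[cbind(ic + 1L, jc + 1L, kc + 1L)]
  fluid <- lab != 1L & lab != 3L &
    cell$solid_frac[cbind(ic + 1L, jc + 1L, kc + 1L)] < 0.5
  px <- px[fluid]; py <- py[fluid]; pz <- pz[fluid]
  vx <- vx[fluid]; vz <- vz[fluid]
  ic <- ic[fluid]; jc <- jc[fluid]; kc <- kc[fluid]
  iu_f <- round(px / h) %% nx
  idx_u <- as.integer(iu_f + nx * (jc + ny * kc))
  jv_f <- pmin(pmax(round(py / h), 0), ny)
  idx_v <- as.integer(ic + nx * (jv_f + (ny + 1) * kc))
  kw_f <- pmin(pmax(round(pz / h), 0), nz)
  idx_w <- as.integer(ic + nx * (jc + ny * kw_f))
  du <- !duplicated(idx_u); dv <- !duplicated(idx_v); dw <- !duplicated(idx_w)
  list(idx_u = idx_u[du], val_u = vx[du], wgt_u = rep(1, sum(du)),
       idx_v = idx_v[dv], wgt_v = rep(1, sum(dv)),
       idx_w = idx_w[dw], val_w = vz[dw], wgt_w = rep(1, sum(dw)))
}

#' Solve the creeping flow at one beat phase
#'
#' @param cell A `unit_cell` from [build_unit_cell()] (its grid spacing must
#'   match `config$h`).
#' @param kin A [beat_kinematics()], or `NULL` for no flagellar forcing
#'   (pure pressure-driven flow).
#' @param config A [solver_config()].
#' @param t Phase time (s).
#' @param init Optional previous `flow_field` used as the initial iterate
#'   (warm start).
#' @return A `flow_field`: staggered velocity arrays `u`, `v`, `w`, pressure
#'   `p`, and solver diagnostics (`iterations`, `residual`, `div_max`,
#'   fluxes `q_in`/`q_top`, energy functionals).
#' @export
solve_phase <- function(cell, kin, config, t = 0, init = NULL) {
  stopifnot(inherits(cell, "unit_cell"), inherits(config, "solver_config"))
  if (abs(cell$h - config$h) > 1e-9) {
    stop("unit cell was discretised at a different h than the solver config",
         call. = FALSE)
  }
  nx <- cell$nx; ny <- cell$ny; nz <- cell$nz
  forcing <- if (is.null(kin)) {
    list(idx_u = integer(0), val_u = numeric(0), wgt_u = numeric(0),
         idx_v = integer(0), wgt_v = numeric(0),
         idx_w = integer(0), val_w = numeric(0), wgt_w = numeric(0))
  } else {
    sheet_forcing(cell, kin, t)
  }
  zero <- function(n) numeric(n)
  u0 <- init$u %||% zero(nx * ny * nz)
  v0 <- init$v %||% zero(nx * (ny + 1) * nz)
  w0 <- init$w %||% zero(nx * ny * (nz + 1))
  p0 <- init$p %||% zero(nx * ny * nz)
  alpha_pen <- default_alpha_pen(cell, config)
  pfrac <- penal_fraction(as.numeric(cell$solid_frac), cell$h, cell$mu,
                          alpha_pen)
  alpha_sheet <- config$alpha_sheet %||% (4000 * cell$mu / cell$h^2)
  out <- stokes_phase_kernel(
    nx, ny, nz, cell$h, cell$mu,
    pfrac, as.numeric(cell$brinkman),
    cell$mem_u_idx, cell$mem_u_coef, cell$mem_w_idx, cell$mem_w_coef,
    alpha_pen, alpha_sheet, config$dp_in,
    forcing$idx_u, forcing$val_u, forcing$wgt_u,
    forcing$idx_v, forcing$wgt_v,
    forcing$idx_w, forcing$val_w, forcing$wgt_w,
    u0, v0, w0, p0,
    config$tol, config$max_iter, config$check_every, config$safety
  )
  if (!isTRUE(out$converged) && out$residual > 50 * config$tol) {
    stop(sprintf(
      "solver did not converge: residual %.3g after %d iterations (tol %.3g)",
      out$residual, out$iterations, config$tol), call. = FALSE)
  }
  structure(c(out, list(t = t, cell_dims = c(nx, ny, nz), h = cell$h)),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Flow field %d x %d x %d (h = %g um), phase t = %g s\n",
              x$cell_dims[1], x$cell_dims[2], x$cell_dims[3], x$h, x$t))
  cat(sprintf("  iterations %d, residual %.3g, max divergence %.3g /s\n",
              x$iterations, x$residual, x$div_max))
  cat(sprintf("  Q_in = %.4g um^3/s, Q_top = %.4g um^3/s\n", x$q_in, x$q_top))
  invisible(x)
}

# Filtration rate: water that crossed the porous collar walls leaves through
# the collar-tip openings, so the net upward flux through each collar's tip
# disc (r <= collar radius, at the collar-tip height) equals the flux drawn
# through the lateral porous surface. Counted once per collar, into the
# collar interior, by continuity.
collar_flux <- function(cell, u, v, w) {
  nx <- cell$nx; ny <- cell$ny; nz <- cell$nz; h <- cell$h
  va <- array(v, dim = c(nx, ny + 1, nz))
  j_face <- round(cell$collar_top / h) + 1   # v-face index nearest the tips
  j_face <- min(max(j_face, 1L), ny + 1L)
  vtip <- va[, j_face, ]
  total <- 0
  for (ci in seq_len(nrow(cell$collars))) {
    dx <- cell$x - cell$collars$x[ci]
    dz <- cell$z - cell$collars$z[ci]
    disc <- outer(dx^2, dz^2, `+`) <= cell$r_col^2
    total <- total + sum(vtip[disc]) * h^2
  }
  total
}

#' Simulate one beat cycle and time-average
#'
#' Solves the quasi-steady flow at `n_phases` equally spaced phases of the
#' beat period (warm-starting each phase from the previous one), and returns
#' phase-averaged fields and rates: the pumping rate `Q_ost` through the
#' ostium mouth, the filtration rate `Q_col` through the collar walls, and
#' the mechanical power spent by the flagella. For an in-phase, common-plane
#' beat the second half-period is the mirror image of the first, so only the
#' first half is solved unless `config$half_period` says otherwise.
#'
#' @param geom A `chamber_geometry`.
#' @param kin A [beat_kinematics()].
#' @param config A [solver_config()].
#' @param cell Optional pre-built `unit_cell` (else built at `config$h`).
#' @param keep_phases Retain the phase-resolved velocity fields (needed for
#'   particle tracking); for half-period runs the second half is
#'   reconstructed by the mirror symmetry.
#' @param quiet Suppress per-phase progress.
#' @return A `chamber_flow` object: `rates` (one-row tibble), `phases`
#'   (per-phase tibble), mean staggered fields `u`, `v`, `w`, `p`, and the
#'   `unit_cell`.
#' @export
solve_cycle <- function(geom, kin, config = solver_config(), cell = NULL,
                        keep_phases = FALSE, quiet = TRUE) {
  cell <- cell %||% build_unit_cell(geom, h = config$h)
  period <- kin$period
  half_ok <- config$half_period %||%
    (length(unique(rep_len(kin$phase, geom$n_choanocytes))) == 1 &&
       length(unique(rep_len(kin$beat_azimuth, geom$n_choanocytes))) == 1)
  n_solve <- if (half_ok) max(2L, config$n_phases %/% 2L) else config$n_phases
  span <- if (half_ok) period / 2 else period
  times <- (seq_len(n_solve) - 1) / n_solve * span

  usum <- 0; vsum <- 0; wsum <- 0; psum <- 0
  phase_rows <- vector("list", n_solve)
  pf <- if (keep_phases) {
    list(u = vector("list", n_solve), v = vector("list", n_solve),
         w = vector("list", n_solve))
  } else NULL
  prev <- NULL
  for (q in seq_len(n_solve)) {
    fld <- solve_phase(cell, kin, config, t = times[q], init = prev)
    prev <- fld
    usum <- usum + fld$u; vsum <- vsum + fld$v
    wsum <- wsum + fld$w; psum <- psum + fld$p
    if (keep_phases) {
      pf$u[[q]] <- fld$u; pf$v[[q]] <- fld$v; pf$w[[q]] <- fld$w
    }
    q_col <- collar_flux(cell, fld$u, fld$v, fld$w)
    phase_rows[[q]] <- tibble::tibble(
      phase = q, t = times[q], q_ost = fld$q_in, q_col = q_col,
      q_top = fld$q_top, mass_imbalance = fld$q_in - fld$q_top,
      power_sheets = fld$power_sheets,
      power_dissipation = fld$phi_visc + fld$phi_brink,
      iterations = fld$iterations, residual = fld$residual,
      div_max = fld$div_max
    )
  }
  phases <- dplyr::bind_rows(phase_rows)
  um <- usum / n_solve; vm <- vsum / n_solve
  wm <- wsum / n_solve; pm <- psum / n_solve
  rates <- tibble::tibble(
    q_ost = mean(phases$q_ost),
    q_col = mean(phases$q_col),
    q_col_mean_field = collar_flux(cell, um, vm, wm),
    mass_imbalance = mean(phases$mass_imbalance),
    power_sheets = mean(phases$power_sheets),
    power_dissipation = mean(phases$power_dissipation),
    n_phases_solved = n_solve,
    half_period = half_ok
  )
  if (keep_phases && half_ok) {
    # second half-period: mirror image about the beat plane normal (x)
    nx <- cell$nx; ny <- cell$ny; nz <- cell$nz
    perm_face <- c(1L, rev(seqapair(2L, nx)))
    perm_cell <- rev(seq_len(nx))
    for (q in seq_len(n_solve)) {
      ua <- array(pf$u[[q]], dim = c(nx, ny, nz))
      va <- array(pf$v[[q]], dim = c(nx, ny + 1, nz))
      wa <- array(pf$w[[q]], dim = c(nx, ny, nz + 1))
      pf$u[[n_solve + q]] <- as.numeric(-ua[perm_face, , ])
      pf$v[[n_solve + q]] <- as.numeric(va[perm_cell, , ])
      pf$w[[n_solve + q]] <- as.numeric(wa[perm_cell, , ])
    }
  }
  structure(
    list(rates = rates, phases = phases, u = um, v = vm, w = wm, p = pm,
         phase_fields = pf, cell = cell, kinematics = kin, config = config),
    class = "chamber_flow"
  )
}

seqapair <- function(from, to) if (to >= from) seq(from, to) else integer(0)

#' @export
print.chamber_flow <- function(x, ...) {
  r <- x$rates
  cat("Time-averaged chamber flow\n")
  cat(sprintf("  Q_ost (pumping rate)    : %.4g um^3/s\n", r$q_ost))
  cat(sprintf("  Q_col (filtration rate) : %.4g um^3/s (x%.2f re-filtration)\n",
              r$q_col, r$q_col / r$q_ost))
  cat(sprintf("  flagellar power         : %.4g pW\n", r$power_sheets * 1e-6))
  cat(sprintf("  phases solved: %d%s\n", r$n_phases_solved,
              if (r$half_period) " (half period, mirror symmetry)" else ""))
  invisible(x)
}

#' @export
tidy.chamber_flow <- function(x, ...) x$phases

#' @export
glance.chamber_flow <- function(x, ...) x$rates

#' Height of the hydrodynamic gasket (stagnation zone)
#'
#' On the vertical line through the ostium centre, finds where the
#' time-averaged vertical velocity changes sign: inflow rising from the
#' ostium meets the backflow descending between the flagella. This stagnation
#' zone is the "hydrodynamic gasket" that forces inhaled water through the
#' collars in the absence of a physical seal.
#'
#' @param flow A `chamber_flow` (or a `flow_field` plus `cell`).
#' @param cell The `unit_cell` (taken from `flow` if omitted).
#' @return One-row tibble: `height` above the chamber floor (um; `NA` if the
#'   vertical velocity never reverses — no hydrodynamic gasket),
#'   `height_over_collar` relative to collar length, `below_collar_tip`.
#' @export
stagnation_height <- function(flow, cell = NULL) {
  cell <- cell %||% flow$cell
  v <- array(flow$v, dim = c(cell$nx, cell$ny + 1, cell$nz))
  ic <- which.min(abs(cell$x - cell$centre[["x"]]))
  kc <- which.min(abs(cell$z - cell$centre[["z"]]))
  # average the four faces around the centre for robustness on even grids
  line <- (v[ic, , kc] + v[min(ic + 1, cell$nx), , kc] +
             v[ic, , min(kc + 1, cell$nz)] +
             v[min(ic + 1, cell$nx), , min(kc + 1, cell$nz)]) / 4
  yf <- (seq_len(cell$ny + 1) - 1) * cell$h   # face heights
  above <- yf > cell$wall_top + 1e-9
  line <- line[above]; yf <- yf[above]
  sign_change <- which(line[-length(line)] > 0 & line[-1] <= 0)
  if (length(sign_change) == 0) {
    return(tibble::tibble(height = NA_real_, height_over_collar = NA_real_,
                          below_collar_tip = NA))
  }
  s <- sign_change[1]
  y0 <- yf[s]; y1 <- yf[s + 1]
  f0 <- line[s]; f1 <- line[s + 1]
  y_star <- y0 + (y1 - y0) * f0 / (f0 - f1)
  height <- y_star - cell$wall_top
  tibble::tibble(
    height = height,
    height_over_collar = height / cell$geom$l_col,
    below_collar_tip = height < cell$geom$l_col
  )
}

#' Straight-tube unit cell (Poiseuille benchmark geometry)
#'
#' A solid block pierced by a circular tube along y, with pressure boundaries
#' at both ends: the textbook Hagen-Poiseuille configuration used to verify
#' the solver against the closed-form flux `Q = pi D^4 dP / (128 mu L)`.
#'
#' @param diameter,length Tube diameter and length (um).
#' @param h Grid spacing (um).
#' @param pad Lateral padding around the tube (um).
#' @param mu Viscosity (Pa s).
#' @return A `unit_cell`-compatible object (no collars, no geometry sweeps).
#' @export
make_tube_cell <- function(diameter, length, h, pad = diameter / 4, mu = 1e-3) {
  r <- diameter / 2
  lx <- 2 * (r + pad)
  nx <- as.integer(round(lx / h)); nz <- nx
  ny <- as.integer(round(length / h))
  lx <- nx * h
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  zc <- (seq_len(nz) - 0.5) * h
  cx <- lx / 2
  rr <- sqrt(outer((xc - cx)^2, (zc - cx)^2, `+`))
  fr <- solidity(rr - r, h)   # solid outside the tube surface
  solid_frac <- array(0, dim = c(nx, ny, nz))
  for (j in seq_len(ny)) solid_frac[, j, ] <- fr
  label <- array(0L, dim = c(nx, ny, nz))
  label[solid_frac > 0.5] <- 1L
  structure(
    list(
      geom = NULL, h = h, mu = mu, nx = nx, ny = ny, nz = nz,
      x = xc, y = yc, z = zc,
      label = label, solid_frac = solid_frac,
      brinkman = array(0, dim = c(nx, ny, nz)),
      mem_u_idx = integer(0), mem_u_coef = numeric(0),
      mem_w_idx = integer(0), mem_w_coef = numeric(0),
      collars = tibble::tibble(collar = integer(0), x = numeric(0),
                               z = numeric(0)),
      r_col = 0, wall_top = 0, collar_top = 0,
      r_ost = r, centre = c(x = cx, z = cx)
    ),
    class = "unit_cell"
  )
}

#' Grid-convergence study
#'
#' Repeats the cycle simulation on a ladder of grids and reports the
#' convergence of the pumping and filtration rates, including the
#' Richardson-style observed order from the three finest grids and the
#' relative change between the two finest.
#'
#' @param geom A `chamber_geometry`.
#' @param kin A [beat_kinematics()].
#' @param h_values Grid spacings (um), coarse to fine; at least 3.
#' @param config Base [solver_config()] (its `h` is overridden).
#' @return A `grid_convergence` list: `table` (tibble of `h`, `q_ost`,
#'   `q_col`), `order` (observed convergence order of `q_ost`),
#'   `finest_rel_change`, `pass` (finest pair within 5%).
#' @export
grid_convergence <- function(geom, kin, h_values, config = solver_config()) {
  stopifnot(length(h_values) >= 3)
  h_values <- sort(h_values, decreasing = TRUE)
  rows <- purrr::map_dfr(h_values, function(h) {
    cfg <- config
    cfg$h <- h
    g <- geom
    # keep the lattice exact; snap the free core height to the grid
    ny <- round((g$l_ost + g$core_height) / h)
    g$core_height <- ny * h - g$l_ost
    g$cell_extent[["y"]] <- g$l_ost + g$core_height
    fl <- solve_cycle(g, kin, cfg)
    dplyr::mutate(fl$rates[, c("q_ost", "q_col")], h = h, .before = 1)
  })
  n <- nrow(rows)
  q <- rows$q_ost
  order_obs <- if (n >= 3) {
    d1 <- abs(q[n - 1] - q[n - 2]); d2 <- abs(q[n] - q[n - 1])
    r1 <- h_values[n - 2] / h_values[n - 1]
    if (d2 > 0) log(d1 / d2) / log(r1) else NA_real_
  } else NA_real_
  rel <- abs(q[n] - q[n - 1]) / abs(q[n])
  structure(list(table = rows, order = order_obs, finest_rel_change = rel,
                 pass = rel < 0.05),
            class = "grid_convergence")
}

#' @export
print.grid_convergence <- function(x, ...) {
  cat("Grid convergence of cycle-averaged rates\n")
  print(as.data.frame(x$table), row.names = FALSE)
  cat(sprintf("  observed order ~ %.2f; finest-pair change %.2f%% (%s)\n",
              x$order, 100 * x$finest_rel_change,
              if (x$pass) "pass" else "not converged"))
  invisible(x)
}

#' Back-pressure samples of the basic pumping unit
#'
#' Runs the cycle simulation of the zero-length-ostium unit at a set of
#' imposed adverse back-pressures, producing the (dP, Q) samples that
#' [characterize_pump()] fits. By linearity two pressures suffice; three
#' give a linearity check.
#'
#' @param geom A `chamber_geometry`; its `l_ost` is forced to zero (the
#'   basic pumping unit is a bare perforation with its choanocytes).
#' @param kin A [beat_kinematics()].
#' @param config A [solver_config()].
#' @param dp Back-pressures (Pa); `NULL` picks `{0, P_est/2, P_est}` from an
#'   initial zero-load solve and a crude stall estimate.
#' @return Tibble with columns `dp`, `q` (ready for [characterize_pump()]).
#' @export
pump_samples <- function(geom, kin, config = solver_config(),
                         dp = NULL, inlet_buffer = 0) {
  geom$l_ost <- 0
  geom$inlet_buffer <- inlet_buffer
  geom$cell_extent[["y"]] <- inlet_buffer + geom$core_height
  cell <- build_unit_cell(geom, h = config$h)
  run_at <- function(dpi) {
    cfg <- config
    cfg$dp_in <- -dpi   # adverse load: inlet pressure below the outlet
    solve_cycle(geom, kin, cfg, cell = cell)$rates$q_ost
  }
  if (is.null(dp)) {
    q0 <- run_at(0)
    # stall estimate from the hole's own orifice-like resistance scale
    p_est <- 2 * q0 * poiseuille_resistance(geom$d_ost, geom$d_ost, cell$mu)
    dp <- c(0, p_est / 2, p_est)
    q <- c(q0, vapply(dp[-1], run_at, numeric(1)))
  } else {
    q <- vapply(dp, run_at, numeric(1))
  }
  tibble::tibble(dp = dp, q = q)
}
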