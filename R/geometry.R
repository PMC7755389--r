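#' Parametric geometry of the flagellated-chamber unit cell
#'
#' Describes the periodic unit cell used throughout the package: one central
#' tubular ostium through the chamber wall, surrounded by 24 choanocyte
#' collars (homogenised porous shells) with their flagella, on a square
#' lattice at the flagellar spacing. The cylindrical wedge of the real
#' chamber is represented as a rectangular slab: periodic along the chamber's
#' long axis (x), symmetry planes on the azimuthal sides (z), the chamber
#' wall as the floor, and an open uniform-pressure top toward the chamber
#' core. All lengths in um.
#'
#' @param chamber_diameter Chamber diameter (context only; the slab cell does
#'   not resolve curvature).
#' @param d_ost,l_ost Ostium diameter and length.
#' @param d_col,l_col Collar (outer) diameter and length.
#' @param d_mv Microvillus diameter.
#' @param l_mv Clear gap between microvilli; may be length-2
#'   `c(base, tip)` for a linearly varying gap along the collar.
#' @param flagella_spacing Centre-to-centre spacing of flagella (lattice
#'   pitch).
#' @param n_choanocytes Choanocytes per ostium; 24 in the reference
#'   configuration (a 5 x 5 lattice with the ostium in the central site).
#' @param gasket Logical; include an impermeable baffle joining the collar
#'   tips (the physical gasket of leucon-type pumping units).
#' @param gasket_height Height of the baffle above the chamber wall;
#'   defaults to `l_col` (collar tips).
#' @param core_height Slab height above the chamber wall to the
#'   uniform-pressure chamber-core boundary.
#' @param inlet_buffer Open water column below the chamber wall (um). Zero
#'   for the standard cell (the uniform-pressure inlet sits at the ostium
#'   mouth); positive when characterising the basic pumping unit, so the
#'   uniform-pressure boundary sits far upstream of the perforation instead
#'   of short-circuiting the pump's near field.
#' @return A `chamber_geometry` object.
#' @seealso [reference_geometry()], [build_unit_cell()], [collar_resistance()]
#' @export
chamber_geometry <- function(chamber_diameter = 85,
                             d_ost = 7.0, l_ost = 3.0,
                             d_col = 2.5, l_col = 4.8,
                             d_mv = 0.1, l_mv = 0.05,
                             flagella_spacing = 5,
                             n_choanocytes = 24,
                             gasket = FALSE,
                             gasket_height = l_col,
                             core_height = 20,
                             inlet_buffer = 0) {
  stopifnot(
    chamber_diameter > 0, d_ost > 0, l_ost >= 0, d_col > 0, l_col > 0,
    d_mv > 0, all(l_mv > 0), length(l_mv) %in% c(1, 2),
    flagella_spacing > 0, n_choanocytes >= 1, core_height > 0
  )
  if (d_col >= flagella_spacing) {
    stop("invalid geometry: collars wider than the flagellar spacing overlap",
         call. = FALSE)
  }
  circumference <- pi * d_col
  if (max(l_mv) >= circumference / 2) {
    stop("invalid geometry: microvillus spacing exceeds half the collar circumference",
         call. = FALSE)
  }
  side <- ceiling(sqrt(n_choanocytes + 1))
  if (side^2 != n_choanocytes + 1 || side %% 2 == 0) {
    stop("n_choanocytes must be odd-side lattice minus the ostium site (e.g. 24)",
         call. = FALSE)
  }
  lx <- side * flagella_spacing
  geom <- structure(
    list(
      chamber_diameter = chamber_diameter,
      d_ost = d_ost, l_ost = l_ost,
      d_col = d_col, l_col = l_col,
      d_mv = d_mv, l_mv = l_mv,
      flagella_spacing = flagella_spacing,
      n_choanocytes = n_choanocytes,
      gasket = gasket, gasket_height = gasket_height,
      core_height = core_height, inlet_buffer = inlet_buffer,
      # unit cell extent: x periodic, y vertical (buffer + wall + core),
      # z symmetric
      cell_extent = c(x = lx, y = inlet_buffer + l_ost + core_height, z = lx),
      lattice_side = side
    ),
    class = "chamber_geometry"
  )
  if (d_ost / 2 + d_col / 2 > sqrt(2) * flagella_spacing) {
    stop("invalid geometry: ostium overlaps the nearest collars", call. = FALSE)
  }
  geom
}

#' Reference chamber geometry
#'
#' The base-case morphology of a calcareous (syconoid) flagellated chamber:
#' 85 um chamber, ostium 7.0 um diameter x 3.0 um length, 24 collars of
#' diameter 2.5 um and length 4.8 um around it at 5 um flagellar spacing,
#' microvilli of 0.1 um diameter with 0.05 um clear gaps, and no physical
#' gasket.
#'
#' @param ... Overrides passed to [chamber_geometry()].
#' @return A `chamber_geometry`.
#' @examples
#' reference_geometry()
#' reference_geometry(gasket = TRUE)        # physical gasket at collar tips
#' reference_geometry(l_ost = 0)            # basic pumping unit (pure hole)
#' @export
reference_geometry <- function(...) {
  chamber_geometry(...)
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat("Flagellated-chamber unit cell (lengths um)\n")
  cat(sprintf("  ostium  : D = %.2f, L = %.2f\n", x$d_ost, x$l_ost))
  cat(sprintf("  collars : %d, D = %.2f, L = %.2f, microvilli %.2f um / gap %s um\n",
              x$n_choanocytes, x$d_col, x$l_col, x$d_mv,
              paste(format(x$l_mv), collapse = " -> ")))
  cat(sprintf("  lattice : %.1f um pitch, cell %g x %g x %g um\n",
              x$flagella_spacing, x$cell_extent[1], x$cell_extent[2],
              x$cell_extent[3]))
  cat(sprintf("  gasket  : %s\n",
              if (x$gasket) sprintf("impermeable baffle at %.2f um", x$gasket_height)
              else "none (hydrodynamic gasket only)"))
  invisible(x)
}

#' Collar (x, z) positions in the unit cell
#'
#' Square lattice at the flagellar spacing with the central site occupied by
#' the ostium.
#'
#' @param geom A `chamber_geometry`.
#' @return Tibble with columns `collar`, `x`, `z`.
#' @export
collar_positions <- function(geom) {
  s <- geom$flagella_spacing
  side <- geom$lattice_side
  coords <- (seq_len(side) - 0.5) * s
  centre <- geom$cell_extent[["x"]] / 2
  grid <- tidyr::expand_grid(x = coords, z = coords)
  grid <- grid[!(abs(grid$x - centre) < s / 4 & abs(grid$z - centre) < s / 4), ]
  tibble::tibble(collar = seq_len(nrow(grid)), x = grid$x, z = grid$z)
}

#' Flow resistance of the microvillar collar wall
#'
#' Homogenises the collar wall — a row of parallel, equally spaced microvilli
#' — into a Darcy-type resistance: the pressure drop for through-flow at
#' speed `U` is `alpha * U * t` with `t = d_mv` the wall thickness. The drag
#' per microvillus per unit length follows the near-contact (lubrication)
#' solution for creeping flow through the gaps of a cylinder row, with a
#' density correction calibrated against resolved two-dimensional Stokes
#' computations of the same configuration (see the methods vignette); it is
#' accurate to within 10% for gap/diameter ratios between 0.25 and 2.
#'
#' @param l_mv Clear gap between adjacent microvilli (um).
#' @param d_mv Microvillus diameter (um).
#' @param mu Dynamic viscosity (Pa s).
#' @return A `collar_permeability` object: `alpha` (Pa s um^-2), `porosity`,
#'   `r_wall = alpha * d_mv` (Pa s um^-1, the full wall resistance), and the
#'   per-microvillus drag coefficient `f_over_mu_u`.
#' @export
collar_resistance <- function(l_mv, d_mv, mu = 1e-3) {
  if (any(l_mv <= 0) || any(d_mv <= 0)) {
    stop("invalid geometry: microvillus gap and diameter must be positive",
         call. = FALSE)
  }
  a <- d_mv / 2          # microvillus radius
  b0 <- l_mv / 2         # half-gap
  pitch <- l_mv + d_mv   # centre-to-centre spacing
  f_lub <- (9 * pi * sqrt(2) / 16) * pitch^2 * sqrt(a) / b0^2.5
  f <- f_lub * (1 + 0.27 * (l_mv / d_mv)^0.58)
  r_wall <- f * mu / pitch          # Pa s um^-1: dp = r_wall * U
  structure(
    list(
      alpha = r_wall / d_mv,
      porosity = l_mv / pitch,
      r_wall = r_wall,
      f_over_mu_u = f,
      l_mv = l_mv, d_mv = d_mv, mu = mu
    ),
    class = "collar_permeability"
  )
}

#' @export
print.collar_permeability <- function(x, ...) {
  cat("Collar wall permeability (cylinder-row homogenisation)\n")
  cat(sprintf("  gap %g um / diameter %g um (gap/diam %.2f), porosity %.2f\n",
              x$l_mv, x$d_mv, x$l_mv / x$d_mv, x$porosity))
  cat(sprintf("  wall resistance dp/U = %.4g Pa s um^-1; alpha = %.4g Pa s um^-2\n",
              x$r_wall, x$alpha))
  invisible(x)
}

# Solidity of a cell from the signed distance to the solid surface
# (positive inside the solid): a linear ramp of width h centred on the
# surface. Partly solid cells receive a finite permeability-type drag (see
# penal_fraction()) so the effective no-slip plane falls on the surface.
solidity <- function(d, h) {
  pmin(1, pmax(0, d / h + 0.5))
}

#' Discretise the unit cell into labelled spatial masks
#'
#' Builds the solver's view of the geometry on a uniform Cartesian grid of
#' spacing `h`: a cell-centred label array (fluid / solid wall / porous
#' collar shell / gasket), a solid volume-fraction array (3^3 subsampling,
#' used for penalization), a Brinkman resistance array for the collar shells
#' (scaled so each one-cell-thick shell carries the physical wall resistance
#' of [collar_resistance()]), and collar metadata. The floor of the cell is
#' the chamber wall of thickness `l_ost` (at least one grid cell) perforated
#' by the central ostium tube; the bottom boundary is the ostium mouth
#' (uniform-pressure inlet), the top boundary the chamber core
#' (uniform-pressure outlet), x is periodic and z has symmetry planes.
#'
#' @param geom A `chamber_geometry`.
#' @param h Grid spacing (um). The cell extent must be (nearly) divisible
#'   by `h`.
#' @param mu Viscosity used for the collar resistance (Pa s).
#' @return A `unit_cell` object: integer `label` array (`0` fluid, `1` solid
#'   wall, `2` collar shell, `3` gasket), `solid_frac`, `brinkman` (Pa s
#'   um^-2 per cell), grid axes, the collar table, and scalar metadata.
#' @export
build_unit_cell <- function(geom, h = 0.5, mu = 1e-3) {
  stopifnot(inherits(geom, "chamber_geometry"), h > 0)
  ext <- geom$cell_extent
  n <- round(ext / h)
  if (max(abs(n * h - ext)) > 1e-6 * h) {
    stop("grid spacing h must divide the cell extent", call. = FALSE)
  }
  nx <- as.integer(n[["x"]]); ny <- as.integer(n[["y"]]); nz <- as.integer(n[["z"]])
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  zc <- (seq_len(nz) - 0.5) * h
  cx <- ext[["x"]] / 2
  cz <- ext[["z"]] / 2
  buffer <- geom$inlet_buffer %||% 0
  # zero-length ostium: a one-cell perforated plate
  wall_top <- buffer + max(geom$l_ost, h)
  r_ost <- geom$d_ost / 2

  label <- array(0L, dim = c(nx, ny, nz))
  solid_frac <- array(0, dim = c(nx, ny, nz))

  # chamber wall with ostium perforation: signed-distance solidity, the wall
  # slab (solid below wall_top) minus the ostium tube (fluid inside r_ost)
  rr <- sqrt(outer((xc - cx)^2, (zc - cz)^2, `+`))   # nx x nz, radial
  fr_radial <- solidity(rr - r_ost, h)               # solid outside the tube
  jwall <- which(yc < wall_top + h & yc > buffer - h)
  for (j in jwall) {
    # solid between the buffer top and the wall top
    fy <- solidity(wall_top - yc[j], h) * solidity(yc[j] - buffer, h)
    if (fy <= 0) next
    solid_frac[, j, ] <- fy * fr_radial
  }
  label[solid_frac > 0.5] <- 1L

  # collar shells: the porous wall is realised as a membrane resistance on
  # the velocity faces the collar cylinder cuts (the physical wall is 0.1 um
  # thick, far below any affordable grid spacing; a one-cell volumetric shell
  # would be several times too thick and rob the confined flagellum of its
  # wall clearance). Each cut face carries the full wall resistance of
  # collar_resistance(): drag coefficient r_wall / h over one-cell depth.
  collars <- collar_positions(geom)
  r_col <- geom$d_col / 2
  j_col <- which(yc > wall_top & yc < wall_top + geom$l_col)
  brinkman <- array(0, dim = c(nx, ny, nz))  # bulk Brinkman unused for collars
  l_mv_at <- function(s_frac) {
    if (length(geom$l_mv) == 2) {
      geom$l_mv[1] + (geom$l_mv[2] - geom$l_mv[1]) * s_frac
    } else geom$l_mv
  }
  # polar sampling marks every cell (and its nearest faces) the circle passes
  # through, so the ring of membrane faces is watertight at any resolution
  theta <- seq(0, 2 * pi, length.out = max(64L, ceiling(6 * pi * r_col / h)))
  theta <- theta[-length(theta)]
  shell_ix <- vector("list", nrow(collars))
  mem_u_idx <- integer(0); mem_u_coef <- numeric(0)
  mem_w_idx <- integer(0); mem_w_coef <- numeric(0)
  r_wall_j <- vapply(j_col, function(j) {
    s_frac <- (yc[j] - wall_top) / geom$l_col
    collar_resistance(l_mv_at(s_frac), geom$d_mv, mu)$r_wall
  }, numeric(1))
  for (c_i in seq_len(nrow(collars))) {
    sx <- collars$x[c_i] + r_col * cos(theta)
    sz <- collars$z[c_i] + r_col * sin(theta)
    ic0 <- pmin(pmax(ceiling(sx / h) - 1L, 0L), nx - 1L)  # 0-based cell
    kc0 <- pmin(pmax(ceiling(sz / h) - 1L, 0L), nz - 1L)
    iu0 <- round(sx / h) %% nx                            # nearest u face
    kw0 <- pmin(pmax(round(sz / h), 0L), nz)              # nearest w face
    cell_idx <- unique(ic0 + nx * kc0)
    if (length(cell_idx) == 0) {
      stop("geometry inconsistency: collar shell unresolved at this h",
           call. = FALSE)
    }
    shell_ix[[c_i]] <- cell_idx
    fu <- unique(iu0 + nx * kc0)   # plan-view u-face keys
    fw <- unique(ic0 + nx * kw0)   # plan-view w-face keys
    for (jj in seq_along(j_col)) {
      j0 <- j_col[jj] - 1L
      coef <- r_wall_j[jj] / h
      mem_u_idx <- c(mem_u_idx, fu %% nx + nx * (j0 + ny * (fu %/% nx)))
      mem_u_coef <- c(mem_u_coef, rep(coef, length(fu)))
      mem_w_idx <- c(mem_w_idx, fw %% nx + nx * (j0 + ny * (fw %/% nx)))
      mem_w_coef <- c(mem_w_coef, rep(coef, length(fw)))
    }
    # label the cut cells as collar shell (masks, capture, reporting)
    for (j in j_col) {
      slab <- label[, j, ]
      free <- cell_idx + 1L
      free <- free[slab[free] == 0L]
      slab[free] <- 2L
      label[, j, ] <- slab
    }
  }
  # collars must be disjoint in plan view
  if (anyDuplicated(unlist(shell_ix))) {
    stop("geometry inconsistency: overlapping collar shells", call. = FALSE)
  }

  # optional physical gasket: impermeable sheet at collar-tip height spanning
  # between collars (collar interiors stay open so flow exits the collar tips)
  if (isTRUE(geom$gasket)) {
    yg <- wall_top + geom$gasket_height
    jg <- which.min(abs(yc - yg))
    rr_min <- array(Inf, dim = c(nx, nz))
    for (c_i in seq_len(nrow(collars))) {
      rr <- sqrt(outer((xc - collars$x[c_i])^2, (zc - collars$z[c_i])^2, `+`))
      rr_min <- pmin(rr_min, rr)
    }
    slab <- label[, jg, ]
    baffle <- rr_min >= r_col - h / 2 & slab == 0L
    slab[baffle] <- 3L
    label[, jg, ] <- slab
    sf <- solid_frac[, jg, ]
    sf[baffle] <- 1
    solid_frac[, jg, ] <- sf
  }

  structure(
    list(
      geom = geom, h = h, mu = mu,
      nx = nx, ny = ny, nz = nz,
      x = xc, y = yc, z = zc,
      label = label, solid_frac = solid_frac, brinkman = brinkman,
      mem_u_idx = as.integer(mem_u_idx), mem_u_coef = mem_u_coef,
      mem_w_idx = as.integer(mem_w_idx), mem_w_coef = mem_w_coef,
      collars = collars, r_col = r_col, wall_top = wall_top,
      collar_top = wall_top + geom$l_col,
      r_ost = r_ost, centre = c(x = cx, z = cz)
    ),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell grid %d x %d x %d (h = %g um)\n", x$nx, x$ny, x$nz, x$h))
  cat(sprintf("  labels: %d fluid, %d wall, %d collar-shell, %d gasket cells\n",
              sum(x$label == 0L), sum(x$label == 1L), sum(x$label == 2L),
              sum(x$label == 3L)))
  invisible(x)
}

#' Tidy cell-label table of a discretised unit cell
#'
#' @param x A `unit_cell`.
#' @param ... Unused.
#' @return Tibble with `x`, `y`, `z`, `label` for non-fluid cells (fluid
#'   cells are omitted to keep the table small).
#' @export
tidy.unit_cell <- function(x, ...) {
  ix <- which(x$label != 0L, arr.ind = TRUE)
  xs <- x$x[ix[, 1]]
  ys <- x$y[ix[, 2]]
  zs <- x$z[ix[, 3]]
  lab <- c("wall", "collar", "gasket")[x$label[ix]]
  tibble::tibble(x = xs, y = ys, z = zs, label = lab)
}
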