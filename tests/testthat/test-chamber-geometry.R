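test_that("reference geometry carries the measured chamber dimensions", {
  g <- reference_geometry()
  expect_equal(g$d_ost, 7.0)
  expect_equal(g$l_ost, 3.0)
  expect_equal(g$d_col, 2.5)
  expect_equal(g$l_col, 4.8)
  expect_equal(g$d_mv, 0.1)
  expect_equal(g$l_mv, 0.05)
  expect_equal(g$flagella_spacing, 5)
  expect_equal(g$n_choanocytes, 24)
  expect_false(g$gasket)
  expect_equal(unname(g$cell_extent[c("x", "z")]), c(25, 25))
})

test_that("geometry invariants are enforced", {
  expect_error(chamber_geometry(d_col = 6), "overlap")
  expect_error(chamber_geometry(d_ost = -1), "d_ost")
  expect_error(chamber_geometry(l_mv = 5), "circumference")
})

test_that("collar lattice holds 24 disjoint collars around the ostium", {
  g <- reference_geometry()
  pos <- collar_positions(g)
  expect_equal(nrow(pos), 24)
  # no collar on the ostium site; pairwise distances at least one pitch
  centre <- g$cell_extent[["x"]] / 2
  expect_true(all(sqrt((pos$x - centre)^2 + (pos$z - centre)^2) >=
                    g$flagella_spacing - 1e-9))
  dmin <- min(stats::dist(cbind(pos$x, pos$z)))
  expect_gte(dmin, g$flagella_spacing - 1e-9)
})

test_that("unit-cell masks partition the cell and resolve the structures", {
  g <- reference_geometry()
  cell <- build_unit_cell(g, h = 0.5)
  expect_setequal(unique(as.integer(cell$label)), c(0L, 1L, 2L))
  # ostium mouth open at the floor: bottom layer has fluid inside r_ost
  floor_open <- cell$solid_frac[, 1, ] < 0.5
  rr <- sqrt(outer((cell$x - cell$centre[["x"]])^2,
                   (cell$z - cell$centre[["z"]])^2, `+`))
  expect_true(all(rr[floor_open] < g$d_ost / 2 + cell$h))
  expect_gt(sum(floor_open), 0)
  # collar shells only at collar heights, carrying membrane resistance
  shell <- which(cell$label == 2L, arr.ind = TRUE)
  ys <- cell$y[shell[, 2]]
  expect_true(all(ys > g$l_ost & ys < g$l_ost + g$l_col + cell$h))
  expect_gt(length(cell$mem_u_idx), 0)
  expect_true(all(cell$mem_u_coef > 0))
  expect_true(all(cell$mem_w_coef > 0))
  # membrane faces sit at collar heights
  j_mem <- (cell$mem_u_idx %/% cell$nx) %% cell$ny + 1
  expect_true(all(cell$y[j_mem] > g$l_ost &
                    cell$y[j_mem] < g$l_ost + g$l_col))
  # shell volume ~ 24 annuli of one-cell wall thickness
  vol_shell <- sum(cell$label == 2L) * cell$h^3
  annulus <- 24 * (pi * ((cell$r_col + cell$h / 2)^2 -
                           (cell$r_col - cell$h / 2)^2)) * g$l_col
  expect_lt(abs(vol_shell / annulus - 1), 0.35)
  # gasket variant adds an impermeable sheet at collar-tip height
  cellg <- build_unit_cell(reference_geometry(gasket = TRUE), h = 0.5)
  gk <- which(cellg$label == 3L, arr.ind = TRUE)
  expect_gt(nrow(gk), 0)
  expect_equal(unique(cellg$y[gk[, 2]]),
               cellg$y[which.min(abs(cellg$y - (g$l_ost + g$l_col)))])
  # zero-length ostium: a one-cell perforated plate
  cell0 <- build_unit_cell(reference_geometry(l_ost = 0), h = 0.5)
  expect_equal(cell0$wall_top, cell0$h)
})

test_that("collar wall resistance matches a resolved 2-D cylinder-row flow", {
  skip_if_not_installed("Matrix")
  # gap/diameter ratios chosen off the formula's calibration points
  cases <- data.frame(g_over_d = c(0.4, 0.75, 1.5), d = c(0.1, 0.1, 0.12))
  for (i in seq_len(nrow(cases))) {
    d <- cases$d[i]; gap <- cases$g_over_d[i] * d
    perm <- collar_resistance(gap, d, mu = 1e-3)
    oracle <- stokes2d_row_drag(a = d / 2, L = d + gap, mu = 1e-3,
                                h = min(gap / 8, d / 16))
    expect_lt(abs(perm$f_over_mu_u / oracle$F_over_muU - 1), 0.1,
              label = sprintf("closed form vs 2-D oracle at g/d = %.2f",
                              cases$g_over_d[i]))
  }
})

test_that("collar resistance scalings: blockage, porosity, profile", {
  p1 <- collar_resistance(0.05, 0.1)
  p2 <- collar_resistance(0.025, 0.1)   # halved gap
  expect_gt(p2$alpha, p1$alpha)
  expect_equal(p1$porosity, 1 / 3)
  # vanishing blockage: alpha -> 0 as the gap opens
  wide <- vapply(c(1, 10, 100), function(l) collar_resistance(l, 0.1)$alpha,
                 numeric(1))
  expect_true(all(diff(wide) < 0))
  expect_lt(wide[3], 1e-3 * p1$alpha)
  expect_error(collar_resistance(0, 0.1), "positive")
  # base->tip porosity profile: tighter tip rows get larger resistance
  g <- reference_geometry(l_mv = c(0.1, 0.033))
  cell <- build_unit_cell(g, h = 0.5)
  ys <- cell$y[(cell$mem_u_idx %/% cell$nx) %% cell$ny + 1]
  b <- cell$mem_u_coef
  expect_gt(mean(b[ys > stats::median(ys)]), mean(b[ys < stats::median(ys)]))
})
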