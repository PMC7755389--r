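test_that("waveform has a clamped base, saturating envelope and exact period", {
  k <- beat_kinematics()
  expect_equal(waveform(0, 0.123, k), 0)
  # base case: past s ~ 3 um the envelope is within 0.1% of a = 1 um
  s <- seq(3, k$l_f, length.out = 50)
  env <- vapply(s, function(si) {
    max(abs(waveform(si, seq(0, k$period, length.out = 400), k)))
  }, numeric(1))
  expect_true(all(env <= 1 + 1e-9))
  expect_true(all(env >= 1 - 1e-3))
  # periodicity to machine precision and zero phase-average at every s
  sgrid <- seq(0, k$l_f, length.out = 17)
  expect_equal(waveform(sgrid, 0.2, k), waveform(sgrid, 0.2 + 1 / k$f, k),
               tolerance = 1e-12)
  tgrid <- seq(0, k$period, length.out = 65)[-65]
  for (si in c(1.3, 7.9, 14.2)) {
    expect_lt(abs(mean(waveform(si, tgrid, k))), 1e-12)
  }
  expect_error(waveform(-1, 0, k), "arclength")
  expect_error(waveform(k$l_f + 1, 0, k), "arclength")
})

test_that("increased-amplitude modulation peaks at 2 um at the tip", {
  k <- beat_kinematics(a = 5, delta = 22)
  tip_env <- 5 * (1 - exp(-(k$l_f / 22)^2))
  expect_equal(tip_env, 2, tolerance = 0.01)
  peak <- max(abs(waveform(k$l_f, seq(0, k$period, length.out = 1000), k)))
  expect_equal(peak, 2, tolerance = 0.01)
  # confined region still fits inside the collar for the base case
  kb <- beat_kinematics()
  g <- reference_geometry()
  s_conf <- seq(0, g$l_col, length.out = 30)
  expect_true(all(abs(waveform(s_conf, 0.01, kb)) <= g$d_col / 2))
})

test_that("sheet markers are inextensible and velocities match finite differences", {
  k <- beat_kinematics()
  g <- reference_geometry()
  st <- sheet_state(0.007, k, g, n_markers = 48)
  expect_equal(dplyr::n_distinct(st$flagellum), 24)
  # centreline length preserved within 1% per flagellum
  one <- dplyr::filter(st, flagellum == 1)
  seg <- sqrt(diff(one$x)^2 + diff(one$y)^2 + diff(one$z)^2)
  expect_equal(sum(seg), k$l_f, tolerance = 0.01)
  # velocities vs central differencing of positions at fixed arclength
  dt <- 1e-6
  stp <- sheet_state(0.007 + dt, k, g, n_markers = 48)
  stm <- sheet_state(0.007 - dt, k, g, n_markers = 48)
  vx_fd <- (stp$x - stm$x) / (2 * dt)
  expect_lt(max(abs(vx_fd - st$vx)), 1e-3 + 1e-6 * max(abs(st$vx)))
  # bases sit on the collar axes at the chamber wall
  bases <- dplyr::filter(st, s == 0)
  pos <- collar_positions(g)
  expect_equal(bases$x, pos$x)
  expect_equal(bases$z, pos$z)
  expect_equal(unique(bases$y), g$l_ost)
})

test_that("presence masks truncate to the confined/unconfined parts", {
  k <- beat_kinematics()
  g <- reference_geometry()
  unc <- sheet_state(0.004, beat_kinematics(presence = "unconfined"), g)
  expect_true(all(unc$y - g$l_ost > g$l_col))
  con <- sheet_state(0.004, beat_kinematics(presence = "confined"), g)
  expect_true(all(con$y - g$l_ost <= g$l_col + 1e-9))
  # piecewise vane: wider above the collar than inside it
  kp <- beat_kinematics(vane_width = c(0.7, 1.4))
  stp <- sheet_state(0.004, kp, g)
  inside <- stp$y - g$l_ost <= g$l_col
  expect_equal(unique(stp$half_width[inside]), 0.35)
  expect_equal(unique(stp$half_width[!inside]), 0.7)
})

test_that("phase offsets and beat planes apply per flagellum", {
  g <- reference_geometry()
  k <- beat_kinematics(phase = c(0, pi), beat_azimuth = c(0, pi / 2))
  st <- sheet_state(0.002, k, g, n_markers = 16)
  f1 <- dplyr::filter(st, flagellum == 1)
  f2 <- dplyr::filter(st, flagellum == 2)
  pos <- collar_positions(g)
  # flagellum 2 beats in the rotated plane: displaced in z, not x
  expect_equal(f2$x, rep(pos$x[2], 16))
  expect_false(isTRUE(all.equal(f2$z, rep(pos$z[2], 16))))
  expect_false(isTRUE(all.equal(f1$x - pos$x[1], f2$z - pos$z[2])))
})
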