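test_that("uniform flow transports particles straight out, none captured", {
  cell <- make_tube_cell(4, 8, h = 0.5)
  nx <- cell$nx; ny <- cell$ny; nz <- cell$nz
  up <- list(u = list(numeric(nx * ny * nz)),
             v = list(rep(100, nx * (ny + 1) * nz)),
             w = list(numeric(nx * ny * (nz + 1))))
  flow <- structure(list(phase_fields = up, cell = cell,
                         kinematics = beat_kinematics(),
                         rates = NULL), class = "chamber_flow")
  ens <- track_particles(flow, n = 200, seed = 4, t_max = 1)
  expect_true(all(ens$fate == "exited"))
  expect_equal(ens$x, ens$x0, tolerance = 1e-8)
  expect_equal(ens$z, ens$z0, tolerance = 1e-8)
  eff <- encounter_efficiency(ens)
  expect_equal(eff$captured, 0)
  expect_equal(eff$efficiency, 0)
})

test_that("base-case tracers encounter the collars at high efficiency", {
  fl <- base_flow()
  ens <- cached("tracers_base", track_particles(fl, n = 800, seed = 1))
  eff <- encounter_efficiency(ens)
  expect_gte(eff$efficiency, 0.95)
  expect_lt(eff$lost_fraction, 0.005)
  # fates partition the ensemble
  expect_equal(eff$captured + eff$exited + eff$remaining + eff$lost, 800)
})

test_that("tracking is deterministic given the seed", {
  fl <- base_flow()
  a <- track_particles(fl, n = 60, seed = 9)
  b <- track_particles(fl, n = 60, seed = 9)
  expect_identical(a$fate, b$fate)
  expect_identical(a$x, b$x)
  c_ <- track_particles(fl, n = 60, seed = 10)
  expect_false(identical(a$x0, c_$x0))
})

test_that("flux-weighted and uniform seeding agree within Monte-Carlo error", {
  fl <- base_flow()
  effs <- sapply(1:3, function(s) {
    ef <- encounter_efficiency(track_particles(fl, n = 700, seed = s,
                                               seeding = "flux"))
    eu <- encounter_efficiency(track_particles(fl, n = 700, seed = s,
                                               seeding = "uniform"))
    c(ef$efficiency, eu$efficiency)
  })
  # both estimators target the same flux-weighted encounter probability
  expect_lt(abs(mean(effs[1, ]) - mean(effs[2, ])), 0.05)
})

test_that("halving the time step changes the efficiency by less than 1%", {
  fl <- base_flow()
  period <- fl$kinematics$period
  e1 <- encounter_efficiency(track_particles(fl, n = 500, seed = 2,
                                             dt = period / 150))
  e2 <- encounter_efficiency(track_particles(fl, n = 500, seed = 2,
                                             dt = period / 300))
  expect_lt(abs(e1$efficiency - e2$efficiency), 0.01)
  # dt guard
  expect_error(track_particles(fl, n = 10, dt = period / 50), "period/100")
})
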