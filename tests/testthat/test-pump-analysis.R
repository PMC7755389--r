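test_that("poiseuille_resistance matches the closed form and its scalings", {
  # reference ostium: 128 * 1e-3 * 3 / (pi * 7^4) = 5.091e-5 Pa s um^-3
  r_ref <- poiseuille_resistance(7.0, 3.0, mu = 1e-3)
  expect_equal(r_ref, 128 * 1e-3 * 3 / (pi * 7^4))
  expect_equal(r_ref * 1e6, 50.91, tolerance = 1e-3)
  # zero-length perforation has no resistance; D^4 scaling
  expect_equal(poiseuille_resistance(7, 0), 0)
  expect_equal(poiseuille_resistance(14, 3), r_ref / 16)
  expect_error(poiseuille_resistance(0, 3), "diameter")
})

test_that("operating point solves the pump/system intersection", {
  pump <- pump_characteristic(q_max = 1114, p_max = 0.058)
  # R^ = 1: half capacity; R^ = 0: full capacity; R^ = 100: impaired
  op1 <- operating_point(pump, 1)
  expect_equal(op1$q_hat_op, 0.5)
  expect_equal(op1$p_hat_op, 0.5)
  expect_equal(op1$q_op, 0.5 * 1114)
  expect_equal(operating_point(pump, 0)$q_hat_op, 1)
  expect_equal(operating_point(pump, 100)$q_hat_op, 1 / 101)
  expect_equal(operating_point(pump, 0.1)$q_hat_op, 1 / 1.1)
  # monotone decreasing in the resistance ratio, with the right limits
  r <- 10^seq(-3, 3, length.out = 25)
  q <- vapply(r, function(x) operating_point(pump, x)$q_hat_op, numeric(1))
  expect_true(all(diff(q) < 0))
  expect_lt(abs(q[1] - 1), 2e-3)
  expect_lt(q[25], 2e-3)
})

test_that("syconoid reference unit sits at R_ost/C_pump ~ 1, half capacity", {
  pump <- pump_characteristic(q_max = 1114, p_max = 0.058)
  expect_equal(report_c_pump(pump$c_pump), 50)
  r_ost <- poiseuille_resistance(7.0, 3.0, mu = 1e-3)
  sys <- system_curve(r_ost, pump)
  expect_equal(round(sys$r_hat), 1)
  op <- operating_point(pump, sys)
  expect_equal(op$q_hat_op, 0.5, tolerance = 0.03)
})

test_that("characterize_pump recovers the line exactly and under noise", {
  q_max <- 800; p_max <- 0.05
  dp <- c(0, 0.02, 0.04)
  q <- q_max * (1 - dp / p_max)
  pc <- characterize_pump(tibble::tibble(dp = dp, q = q))
  expect_equal(pc$q_max, q_max)
  expect_equal(pc$p_max, p_max)
  expect_gt(pc$r_squared, 0.999)
  # two samples define the line exactly
  pc2 <- characterize_pump(tibble::tibble(dp = dp[-2], q = q[-2]))
  expect_equal(pc2$q_max, q_max)
  # 1% multiplicative noise: intercepts recovered to < 3%
  withr::with_seed(7, {
    for (rep in 1:5) {
      qn <- q * (1 + stats::rnorm(3, 0, 0.01))
      pcn <- characterize_pump(tibble::tibble(dp = dp, q = qn),
                               min_r_squared = 0)
      expect_lt(abs(pcn$q_max / q_max - 1), 0.03)
      expect_lt(abs(pcn$p_max / p_max - 1), 0.03)
    }
  })
  # scaling all rates doubles both intercepts, C_pump unchanged
  pcs <- characterize_pump(tibble::tibble(dp = 2 * dp, q = 2 * q))
  expect_equal(pcs$q_max, 2 * q_max)
  expect_equal(pcs$p_max, 2 * p_max)
  expect_equal(pcs$c_pump, pc$c_pump)
  expect_error(characterize_pump(tibble::tibble(dp = c(0, 0), q = c(1, 2))),
               "distinct")
})

test_that("characteristic curves pass through the operating points", {
  cc <- characteristic_curves(c(0.1, 1, 100))
  pump_line <- dplyr::filter(cc$curves, curve == "pump")
  expect_equal(range(pump_line$q_hat), c(0, 1))
  expect_equal(pump_line$p_hat, 1 - pump_line$q_hat)
  ops <- cc$operating_points
  # intersections lie on both lines to machine precision
  expect_equal(ops$p_hat_op, 1 - ops$q_hat_op)
  expect_equal(ops$p_hat_op, ops$r_hat * ops$q_hat_op)
  expect_equal(ops$q_hat_op[ops$r_hat == 0.1], 1 / 1.1)
})
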