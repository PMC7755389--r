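test_that("excurrent flow is jet speed times osculum area", {
  m <- tibble::tibble(sponge = "s1", distance_mm = 10, time_s = 2,
                      osculum_area_mm2 = 1)
  f <- excurrent_flow(m)
  expect_equal(f$flow_mm3_s, 5)
  expect_equal(f$flow_um3_s, 5e9)
  # replicates at equal speed give the same flow as either alone
  m2 <- tibble::tibble(sponge = "s1", distance_mm = c(10, 20),
                       time_s = c(2, 4), osculum_area_mm2 = 1)
  expect_equal(excurrent_flow(m2)$flow_mm3_s, 5)
  expect_equal(excurrent_flow(m2)$n_replicates, 2L)
  # degenerate inputs
  expect_equal(excurrent_flow(dplyr::mutate(m, osculum_area_mm2 = 0))$flow_mm3_s, 0)
  expect_error(excurrent_flow(dplyr::mutate(m, time_s = 0)), "time")
  expect_error(excurrent_flow(m[, -3]), "time_s")
})

test_that("per-unit rates divide flux among ostia and choanocytes", {
  r <- per_unit_rates(1151 * 1000, n_ostia = 1000)
  expect_equal(r$q_ost_um3_s, 1151)
  expect_equal(round(r$q_ch_um3_s), 48)
  expect_true(r$q_ch_in_leucon_range)  # published range 17-236 um^3/s
  expect_false(per_unit_rates(10 * 24, 10)$q_ch_in_leucon_range)
  expect_error(per_unit_rates(100, 0), "positive")
})

test_that("bead calibration converts counts to concentrations", {
  s <- tibble::tibble(bead_count = 500, euk = 10, hna = 100, lna = 2000)
  cc <- bead_calibrated_concentration(s, bead_stock_per_ul = 100)
  expect_equal(cc$volume_ul, 5)
  expect_equal(cc$lna_per_ul, 400)
  # ratio invariance: doubling all counts leaves concentrations unchanged
  cc2 <- bead_calibrated_concentration(
    dplyr::mutate(s, dplyr::across(dplyr::everything(), ~ .x * 2)), 100)
  expect_equal(cc2$lna_per_ul, cc$lna_per_ul)
  expect_equal(cc2$euk_per_ul, cc$euk_per_ul)
  # zero class events give zero concentration; zero beads are an error
  expect_equal(bead_calibrated_concentration(
    dplyr::mutate(s, euk = 0), 100)$euk_per_ul, 0)
  expect_error(bead_calibrated_concentration(
    dplyr::mutate(s, bead_count = 0), 100), "calibration")
})

test_that("retention efficiency is 100 (Cin - Cex) / Cin, sign preserved", {
  expect_equal(retention_efficiency(100, 40), 60)
  expect_equal(retention_efficiency(100, 0), 100)
  expect_equal(retention_efficiency(100, 100), 0)
  expect_equal(retention_efficiency(100, 130), -30)  # not clipped
  # scale invariance in concentration units
  expect_equal(retention_efficiency(5, 2), retention_efficiency(5000, 2000))
  expect_error(retention_efficiency(0, 1), "positive")
})

test_that("paired In-Ex pipeline computes per-pair retentions", {
  inex <- tibble::tibble(
    sponge = rep("s1", 4), pair = rep(1:2, each = 2),
    direction = rep(c("in", "ex"), 2),
    bead_count = c(500, 500, 250, 500),
    euk = c(100, 2, 50, 4), hna = c(1000, 20, 500, 40),
    lna = c(2000, 800, 1000, 800)
  )
  ret <- inex_retention(inex, bead_stock_per_ul = 100)
  expect_equal(nrow(ret), 6)  # 2 pairs x 3 classes
  lna1 <- ret$retention_pct[ret$class == "lna" & ret$pair == 1]
  expect_equal(lna1, 60)  # 400 in, 160 ex per uL
  # pair 2 has half the analysed volume on the inhaled side
  euk2 <- ret$retention_pct[ret$class == "euk" & ret$pair == 2]
  expect_equal(euk2, 100 * (20 - 0.8) / 20)
  expect_error(inex_retention(dplyr::mutate(inex, direction = "x"),
                              100), "malformed")
})

test_that("box summary follows type-7 quartiles and the 1.5 IQR whisker rule", {
  ret <- tibble::tibble(class = "lna", retention_pct = c(50, 55, 60, 65, 70))
  s <- retention_summary(ret)
  expect_equal(s$median, 60)
  expect_equal(s$q1, 55)
  expect_equal(s$q3, 65)
  expect_equal(s$whisker_lo, 50)   # never beyond the data extremes
  expect_equal(s$whisker_hi, 70)
  expect_equal(s$n_outliers, 0L)
  expect_equal(s$mean, 60)
  expect_equal(s$se, stats::sd(c(50, 55, 60, 65, 70)) / sqrt(5))

  # an extreme point beyond 1.5 IQR is flagged and excluded from whiskers
  v <- c(50, 55, 60, 65, 70, 60 + 10 * 15)
  s2 <- retention_summary(tibble::tibble(class = "lna", retention_pct = v))
  expect_equal(s2$n_outliers, 1L)
  expect_equal(s2$outliers[[1]], 210)
  expect_lte(s2$whisker_hi, 70)

  # all equal: zero-width box, no outliers
  s3 <- retention_summary(tibble::tibble(class = "euk",
                                         retention_pct = rep(97, 5)))
  expect_equal(s3$iqr, 0)
  expect_equal(s3$n_outliers, 0L)
  # every point is either inside the whiskers or an outlier
  expect_equal(s2$n_outliers + sum(v >= s2$whisker_lo & v <= s2$whisker_hi),
               length(v))
})
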