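test_that("tidiers expose pump characteristics as tidy tables", {
  pc <- characterize_pump(tibble::tibble(dp = c(0, 0.02, 0.04),
                                         q = c(800, 480, 160)))
  td <- tidy(pc)
  expect_equal(td$term, c("q_max", "p_max", "c_pump"))
  expect_equal(td$estimate[1], 800)
  gl <- glance(pc)
  expect_equal(gl$c_pump_upa, 1e6 * pc$c_pump)
  expect_equal(gl$n_samples, 3L)
})

test_that("autoplot methods return ggplot objects", {
  p1 <- autoplot(characteristic_curves())
  expect_s3_class(p1, "ggplot")
  rs <- retention_summary(tibble::tibble(
    class = rep(c("euk", "lna"), each = 5),
    retention_pct = c(96, 97, 98, 99, 98, 50, 55, 60, 65, 70)))
  p2 <- autoplot(rs)
  expect_s3_class(p2, "ggplot")
  # flow-field slice plot from a cached cycle
  p3 <- autoplot(base_flow(), plane = "xy")
  expect_s3_class(p3, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p3))
})

test_that("unit-cell masks tidy into a labelled table", {
  cell <- build_unit_cell(reference_geometry(), h = 1)
  td <- tidy(cell)
  expect_setequal(unique(td$label), c("wall", "collar"))
  expect_true(all(c("x", "y", "z") %in% names(td)))
})
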