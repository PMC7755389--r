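test_that("generated In-Ex tables are deterministic, integer and well-formed", {
  cfg <- generator_config(seed = 42)
  a <- generate_inex(cfg)
  b <- generate_inex(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), cfg$n_sponges * cfg$pairs_per_sponge * 2)
  counts <- as.matrix(a[, c("bead_count", "euk", "hna", "lna")])
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  expect_setequal(unique(a$direction), c("in", "ex"))
  # a different seed gives different draws
  expect_false(identical(a, generate_inex(generator_config(seed = 43))))
})

test_that("generated flux tables respect the measurement conventions", {
  cfg <- generator_config(seed = 11)
  f <- generate_flux(cfg)
  expect_identical(f, generate_flux(cfg))
  expect_true(all(f$distance_mm >= 10 & f$distance_mm <= 20))
  expect_true(all(f$time_s > 0))
  reps <- dplyr::count(f, sponge)
  expect_true(all(reps$n >= 5 & reps$n <= 10))
  # one osculum area per sponge
  areas <- dplyr::n_distinct(f$osculum_area_mm2[f$sponge == f$sponge[1]])
  expect_equal(areas, 1L)
  # zero jet-speed spread makes replicate speeds identical
  f0 <- generate_flux(generator_config(seed = 5, dye_speed_sd_mm_s = 0))
  sp <- f0$distance_mm / f0$time_s
  expect_lt(max(tapply(sp, f0$sponge, stats::sd)), 1e-9)
  # recovered flow approaches speed mean x area mean over many sponges
  fbig <- generate_flux(generator_config(seed = 2, n_sponges = 200,
                                         dye_speed_sd_mm_s = 0.1,
                                         osculum_area_sd_mm2 = 0.02))
  fl <- excurrent_flow(fbig)
  expect_equal(mean(fl$flow_mm3_s), 5 * 1, tolerance = 0.05)
})

test_that("estimator recovers the configured true retentions end to end", {
  cfg <- generator_config(seed = 1)
  ret <- inex_retention(generate_inex(cfg), cfg$bead_stock_per_ul)
  s <- retention_summary(ret[, c("class", "retention_pct")])
  for (cl in names(cfg$true_retention)) {
    row <- s[s$class == cl, ]
    # class mean within 2 generator-level standard errors of the truth
    se_gen <- cfg$retention_sd / sqrt(cfg$n_sponges)
    expect_lt(abs(row$mean - cfg$true_retention[[cl]]), 2 * se_gen)
  }
  # total retention with no between-sponge spread: exhaled counts are
  # contamination-level only
  ex_euk <- generate_inex(generator_config(seed = 3, retention_sd = 0,
      true_retention = c(euk = 100, hna = 98, lna = 60)))
  ex_euk <- ex_euk$euk[ex_euk$direction == "ex"]
  expect_lt(mean(ex_euk), 3)  # Poisson(contamination = 1)
})
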