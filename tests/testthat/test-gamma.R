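test_that("criteria are validated and the fine grid covers the same extent", {
  expect_error(gamma_criteria(dta = -1), "positive")
  expect_error(gamma_criteria(fine_spacing = 0.8), "dta/2")

  d <- volume_image(array(runif(11^3, 0, 20), c(11, 11, 11)), c(1, 1, 1),
                    c(-5, -5, -5), "DOSE")
  f <- resample_dose_fine(d, 0.2)
  expect_equal(dim(f$voxels), rep(5 * (11 - 1) + 1, 3))
  expect_equal(f$origin, d$origin)
  expect_equal(f$spacing, rep(0.2, 3))
  # voxel-center extent preserved
  expect_equal(max(grid_axes(f)$x), max(grid_axes(d)$x))

  # trilinear reproduces a linear dose field exactly
  ax <- (0:10)
  ramp <- volume_image(array(rep(ax, 11 * 11), c(11, 11, 11)), c(1, 1, 1),
                       c(0, 0, 0), "DOSE")
  fr <- resample_dose_fine(ramp, 0.5)
  expect_equal(fr$voxels[, 1, 1], seq(0, 10, by = 0.5), tolerance = 1e-12)

  # constant stays constant
  const <- volume_image(array(7, c(6, 6, 6)), c(1, 1, 1), c(0, 0, 0), "DOSE")
  expect_equal(unique(as.numeric(resample_dose_fine(const, 0.25)$voxels)), 7)
})

test_that("gamma of a dose against itself is identically zero", {
  tg <- target(c(0, 0, 0), 6)
  d <- make_srs_dose(tg, dose_spec(dims = c(30, 30, 30)))
  f <- resample_dose_fine(d, 0.2)
  g <- gamma_map(f, f)
  expect_equal(max(g$gamma, na.rm = TRUE), 0)
  expect_equal(g$passing_rate, 1)
  # threshold masks low doses: evaluated points carry gamma, others NA
  expect_true(all(is.na(g$gamma[f$voxels <= 0.1 * max(f$voxels)])))
  expect_equal(sum(!is.na(g$gamma)), g$n_evaluated)
})

test_that("uniform dose offsets give the closed-form gamma on the plateau", {
  tg <- target(c(0, 0, 0), 6)
  d <- make_srs_dose(tg, dose_spec(dims = c(30, 30, 30)))
  f <- resample_dose_fine(d, 0.2)
  ci <- round((tg$centroid - f$origin) / f$spacing) + 1

  up <- f; up$voxels <- f$voxels + 0.005 * max(f$voxels)
  g1 <- gamma_map(f, up)
  expect_equal(g1$gamma[ci[1], ci[2], ci[3]], 0.5, tolerance = 1e-9)
  expect_equal(g1$passing_rate, 1)

  up2 <- f; up2$voxels <- f$voxels + 0.02 * max(f$voxels)
  g2 <- gamma_map(f, up2)
  # plateau interior: no gradient can rescue a 2% offset at 1% criterion
  expect_equal(g2$gamma[ci[1], ci[2], ci[3]], 2, tolerance = 1e-9)
  expect_lt(g2$passing_rate, 1)

  # loosening either criterion never un-passes a point (monotonicity)
  g_loose_dd <- gamma_map(f, up2, gamma_criteria(dose_diff = 3))
  pass2 <- !is.na(g2$gamma) & g2$gamma <= 1
  pass_loose <- !is.na(g_loose_dd$gamma) & g_loose_dd$gamma <= 1
  expect_true(all(pass_loose[pass2]))
  g_loose_dta <- gamma_map(f, up2, gamma_criteria(dta = 2, fine_spacing = 0.2))
  pass_dta <- !is.na(g_loose_dta$gamma) & g_loose_dta$gamma <= 1
  expect_true(all(pass_dta[pass2]))
})

test_that("optimized gamma equals the exhaustive brute-force oracle", {
  crit <- gamma_criteria(dta = 1, dose_diff = 1, threshold = 10,
                         fine_spacing = 0.5, search_radius = 30)
  for (seed in 1:10) {
    pair <- random_dose_pair(seed)
    gm <- gamma_map(pair$ref, pair$ev, crit)
    gb <- gamma_brute(pair$ref, pair$ev, crit)
    expect_lt(max(abs(gm$gamma - gb$gamma), na.rm = TRUE), 1e-6)
    expect_equal(gm$passing_rate, gb$passing_rate)
    expect_equal(gm$n_evaluated, gb$n_evaluated)
  }
  big <- volume_image(array(1, c(70, 70, 70)), c(1, 1, 1), modality = "DOSE")
  expect_error(gamma_brute(big, big), "small grids")
})

test_that("a sub-DTA rigid shift with unchanged dose values passes fully", {
  tg <- target(c(0, 0, 0), 5)
  d <- make_srs_dose(tg, dose_spec(dims = c(26, 26, 26)))
  crit <- gamma_criteria(fine_spacing = 0.1)
  f <- resample_dose_fine(d, crit$fine_spacing)
  # rigid 0.5 mm shift = 5 fine voxels along x, dose values untouched
  s <- 5L
  ev <- f
  ev$voxels <- array(0, dim(f$voxels))
  ev$voxels[(s + 1):dim(f$voxels)[1], , ] <-
    f$voxels[1:(dim(f$voxels)[1] - s), , ]
  g <- gamma_map(f, ev, crit)
  expect_equal(g$passing_rate, 1)
  expect_lte(max(g$gamma, na.rm = TRUE), 0.5 + 1e-9)
})

test_that("gamma reduces to the dose-difference ratio on flat fields", {
  a <- volume_image(array(10, c(4, 4, 4)), c(1, 1, 1), modality = "DOSE")
  b <- volume_image(array(10.35, c(4, 4, 4)), c(1, 1, 1), modality = "DOSE")
  g <- gamma_map(a, b, gamma_criteria(dta = 1, dose_diff = 1, threshold = 10,
                                      fine_spacing = 0.5))
  # |dD| / (1% of 10 Gy) = 0.35 / 0.1 = 3.5 everywhere
  expect_equal(unique(round(as.numeric(g$gamma), 9)), 3.5)
  expect_error(gamma_map(a, volume_image(array(1, c(5, 5, 5)), c(1, 1, 1),
                                         modality = "DOSE")), "share")
})

test_that("summarize_gamma aggregates passing rates", {
  s <- summarize_gamma(c(1, 1, 1))
  expect_equal(s$mean, 1); expect_equal(s$sd, 0)
  s2 <- summarize_gamma(c(0.9, 1))
  expect_equal(s2$mean, 0.95)
  expect_equal(c(s2$min, s2$max), c(0.9, 1))
  expect_error(summarize_gamma(numeric(0)), "no gamma")
})
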