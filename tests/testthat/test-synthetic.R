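test_that("phantom tissue values and masks follow the analytic geometry", {
  ph <- clean_phantom()
  spec <- ph$spec
  ctr_idx <- round((c(0, 0, 0) - spec$origin) / spec$spacing) + 1
  expect_equal(ph$ct$voxels[ctr_idx[1], ctr_idx[2], ctr_idx[3]], spec$hu_brain)

  tg <- spec$targets[[1]]
  ti <- round((tg$centroid - spec$origin) / spec$spacing) + 1
  expect_equal(ph$ct$voxels[ti[1], ti[2], ti[3]],
               spec$hu_brain + spec$hu_target_enhancement)

  # voxelized GTV volume vs analytic sphere volume
  vox_vol <- sum(ph$gtv[[1]]) * prod(spec$spacing)
  expect_lt(abs(vox_vol - 4 / 3 * pi * tg$gtv_radius^3) /
              (4 / 3 * pi * tg$gtv_radius^3), 0.05)

  # masks partition: skull and brain disjoint, GTV inside brain
  expect_false(any(ph$skull & ph$brain))
  expect_true(all(ph$brain[ph$gtv[[1]]]))

  expect_error(make_head_phantom(
    phantom_spec(targets = list(target(c(80, 0, 0), 8)))), "inside")
})

test_that("phantom generation is deterministic given spec and seed", {
  a <- make_head_phantom(phantom_spec(noise_sigma = 4, seed = 11))
  b <- make_head_phantom(phantom_spec(noise_sigma = 4, seed = 11))
  c <- make_head_phantom(phantom_spec(noise_sigma = 4, seed = 12))
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_false(identical(a$ct$voxels, c$ct$voxels))
  expect_gte(min(a$ct$voxels), -1000)  # HU floor
})

test_that("simulate_rescan moves the skull rigidly and adds seeded noise", {
  ph <- clean_phantom()
  # identity, no noise, no perturbation: bit-identical
  rs0 <- simulate_rescan(ph, rigid_transform(), noise_sigma = 0,
                         local_hu_offset = 0)
  expect_identical(rs0$voxels, ph$ct$voxels)

  # pure translation displaces the bone centroid by |t|
  rs <- simulate_rescan(ph, rigid_transform(3, -2, 1), noise_sigma = 0,
                        local_hu_offset = 0)
  centroid <- function(img) {
    idx <- which(img$voxels > 300, arr.ind = TRUE)
    ax <- grid_axes(img)
    c(mean(ax$x[idx[, 1]]), mean(ax$y[idx[, 2]]), mean(ax$z[idx[, 3]]))
  }
  shift <- centroid(rs) - centroid(ph$ct)
  expect_lt(abs(sqrt(sum(shift^2)) - sqrt(3^2 + 2^2 + 1^2)),
            0.5 * min(ph$ct$spacing))

  # identity path: sample s.d. of the added noise matches sigma within 10%
  rs2 <- simulate_rescan(ph, rigid_transform(), noise_sigma = 5,
                         local_hu_offset = 0, seed = 4)
  d <- (rs2$voxels - ph$ct$voxels)[ph$brain & !ph$gtv[[1]]]
  expect_lt(abs(stats::sd(d) - 5) / 5, 0.1)

  # local contrast/edema surrogate raises brain HU near the target only
  rs3 <- simulate_rescan(ph, rigid_transform(), noise_sigma = 0,
                         local_hu_offset = 20)
  d3 <- rs3$voxels - ph$ct$voxels
  tg <- ph$spec$targets[[1]]
  expect_equal(max(d3), 20)
  expect_equal(d3[ph$gtv[[1]]], rep(20, sum(ph$gtv[[1]])))
  far <- ph$brain & srsrescan:::ellipsoid_field(
    ph$spec, rep(3 * tg$gtv_radius, 3), tg$centroid) > 1
  expect_equal(unique(d3[far]), 0)
  expect_equal(unique(d3[ph$skull]), 0)  # skull untouched
})

test_that("derived MR has T1-like contrast and is deterministic", {
  ph <- clean_phantom()
  mr <- derive_mr(ph$ct)
  expect_identical(mr$voxels, derive_mr(ph$ct)$voxels)
  expect_lt(mean(mr$voxels[ph$skull]), mean(mr$voxels[ph$brain]))
  # contrast-enhancing GTV is the brightest tissue
  expect_gt(mean(mr$voxels[ph$gtv[[1]]]),
            mean(mr$voxels[ph$brain & !ph$gtv[[1]]]))
  expect_identical(mr$modality, "MR")
})

test_that("MR is more similar to its source CT than to different anatomy", {
  ph <- clean_phantom()
  mr <- derive_mr(ph$ct)
  other <- other_phantom()
  expect_gt(mutual_information_normalized(mr, ph$ct),
            mutual_information_normalized(mr, other$ct))
})

test_that("the analytic SRS dose meets the plan objective", {
  tg <- target(c(30, 0, 10), 8)
  spec <- dose_spec()
  d <- make_srs_dose(tg, spec)
  at_centroid <- sample_volume(d, matrix(tg$centroid, 1))$values
  expect_identical(at_centroid, 20)  # prescription exactly (plateau)
  expect_gte(coverage(d, tg$ptv_radius, tg$centroid, spec$prescription), 0.98)

  # closed form: 10% of max at r = ptv + sigma * sqrt(2 ln 10)
  r10 <- tg$ptv_radius + spec$falloff_sigma * sqrt(2 * log(10))
  pt <- tg$centroid + c(r10, 0, 0)
  analytic <- spec$prescription *
    exp(-(r10 - tg$ptv_radius)^2 / (2 * spec$falloff_sigma^2))
  expect_equal(analytic, 2, tolerance = 1e-9)

  # radially monotone non-increasing outside the PTV (along an axis ray)
  ax <- grid_axes(d)
  jmid <- which.min(abs(ax$y - tg$centroid[2]))
  kmid <- which.min(abs(ax$z - tg$centroid[3]))
  prof <- d$voxels[, jmid, kmid][ax$x >= tg$centroid[1] + tg$ptv_radius]
  expect_true(all(diff(prof) <= 1e-12))
})

test_that("coverage counts voxel centers inside the sphere", {
  g <- volume_image(array(20, c(21, 21, 21)), c(0.5, 0.5, 0.5),
                    c(-5, -5, -5), "DOSE")
  expect_equal(coverage(g, 4, c(0, 0, 0), 20), 1)
  z <- g; z$voxels[] <- 0
  expect_equal(coverage(z, 4, c(0, 0, 0), 20), 0)
  # hard-edged sphere of dose vs matching spherical target
  ax <- grid_axes(g)
  r <- sqrt(outer(outer(ax$x^2, ax$y^2, `+`), ax$z^2, `+`))
  s <- g; s$voxels <- array(ifelse(r <= 5, 20, 0), dim(g$voxels))
  expect_gte(coverage(s, 5, c(0, 0, 0), 20), 0.95)
  expect_error(coverage(g, 0.1, c(50, 50, 50), 20), "inside")
})
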