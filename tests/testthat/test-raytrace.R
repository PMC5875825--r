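test_that("the 16 ray directions have the prescribed structure", {
  d <- ray_directions()
  expect_equal(nrow(d), 16)
  expect_equal(sqrt(rowSums(d^2)), rep(1, 16), tolerance = 1e-9)
  # transverse octet spans the plane and cancels by symmetry
  expect_equal(d[1:8, 3], rep(0, 16 / 2), tolerance = 1e-12)
  expect_equal(colSums(d[1:8, ]), c(0, 0, 0), tolerance = 1e-12)
  # oblique octet elevated 45 degrees superiorly
  expect_equal(d[9:16, 3], rep(sin(pi / 4), 8), tolerance = 1e-12)
  expect_equal(d[1, ], c(1, 0, 0), tolerance = 1e-12)  # azimuth 0 = +x

  dalt <- ray_directions("alternating")
  expect_equal(dalt[9:16, 3], rep(c(1, -1), 4) * sin(pi / 4),
               tolerance = 1e-12)
})

test_that("traced distances match the closed-form ray-ellipsoid oracle", {
  ph <- clean_phantom()
  semi <- inner_semi_axes()
  dirs <- ray_directions()
  half_voxel <- max_voxel_path(ph$ct$spacing) / 2

  for (c0 in list(c(0, 0, 0), c(30, 0, 10), c(-20, 25, -15))) {
    prof <- skull_profile(ph$ct, target(c0, 5))
    oracle <- apply(dirs, 1, function(u) ray_ellipsoid_distance(c0, u, semi))
    expect_true(all(prof$valid))
    expect_lt(max(abs(prof$distance_mm - oracle)), half_voxel)
  }

  # offset along +x: the +x ray shortens and the -x ray lengthens
  p0 <- skull_profile(ph$ct, target(c(0, 0, 0), 5))
  p1 <- skull_profile(ph$ct, target(c(10, 0, 0), 5))
  expect_lt(abs((p0$distance_mm[1] - p1$distance_mm[1]) - 10), half_voxel)
  expect_lt(abs((p1$distance_mm[5] - p0$distance_mm[5]) - 10), half_voxel)

  # ellipsoid anisotropy: +x vs +y distances differ by the semi-axis gap
  expect_lt(abs((p0$distance_mm[3] - p0$distance_mm[1]) - (semi[2] - semi[1])),
            2 * half_voxel)
})

test_that("rays that never meet bone report failure, not an error", {
  # open shell: skull removed on the +x side
  ph <- clean_phantom()
  open_ct <- ph$ct
  ax <- grid_axes(open_ct)
  open_ct$voxels[ax$x > 70, , ] <- ph$spec$hu_brain
  d <- trace_to_skull(open_ct, c(0, 0, 0), c(1, 0, 0))
  expect_true(is.na(d))
  expect_true(attr(d, "failed"))
  # the -x ray is unaffected
  expect_false(is.na(trace_to_skull(open_ct, c(0, 0, 0), c(-1, 0, 0))))

  prof <- skull_profile(open_ct, target(c(0, 0, 0), 5))
  expect_false(all(prof$valid))
  expect_error(trace_to_skull(ph$ct, c(0, 0, 0), c(2, 0, 0)), "unit")
  expect_error(trace_to_skull(ph$ct, c(500, 0, 0), c(1, 0, 0)), "outside")
})

test_that("profiles are deterministic and rotation-equivariant", {
  ph <- clean_phantom()
  tg <- target(c(20, -10, 5), 5)
  p1 <- skull_profile(ph$ct, tg)
  p2 <- skull_profile(ph$ct, tg)
  expect_identical(p1$distance_mm, p2$distance_mm)

  # rotate the anatomy and the probe directions together: distances persist
  ang <- 25
  rot <- rigid_transform(roll = ang)  # about z through the skull center
  rotated <- resample_volume(ph$ct, invert_transform(rot))
  dirs <- ray_directions()
  c_rot <- as.numeric(transform_points(rot, tg$centroid))
  for (r in c(1, 2, 6, 9, 14)) {
    u_rot <- as.numeric(rotation_matrix(rot) %*% dirs[r, ])
    d_rot <- trace_to_skull(rotated, c_rot, u_rot)
    expect_lt(abs(d_rot - p1$distance_mm[r]), 0.3)
  }
})

test_that("profile differences quantify skull change", {
  ph <- clean_phantom()
  tg <- target(c(0, 0, 0), 5)
  p <- skull_profile(ph$ct, tg)
  self <- profile_difference(p, p)
  expect_equal(self$per_ray_abs_diff, rep(0, 16))
  expect_equal(self$mean_abs_diff, 0)
  expect_equal(self$n_valid_rays, 16)

  # inner surface grown by 2 mm (thinner skull): differences = 2 mm
  grown <- fixture("grown_phantom", make_head_phantom(
    phantom_spec(skull_thickness = 4)))
  pg <- skull_profile(grown$ct, tg)
  cmp <- profile_difference(p, pg)
  expect_lt(abs(cmp$mean_abs_diff - 2), max_voxel_path(ph$ct$spacing) / 2)
  expect_gte(cmp$max_abs_diff, cmp$mean_abs_diff)

  # rigid motion + registration-free resample back: skull is unchanged
  Tt <- rigid_transform(2, -1.5, 1, 1, -1, 0.5, center = image_center(ph$ct))
  moved <- simulate_rescan(ph, Tt, noise_sigma = 0, local_hu_offset = 0)
  back <- resample_volume(moved, Tt, target_grid = ph$ct)
  pb <- skull_profile(back, tg)
  cmp2 <- profile_difference(p, pb)
  expect_lt(cmp2$mean_abs_diff, 0.5)

  expect_error(profile_difference(p, skull_profile(ph$ct, target(c(0, 0, 0), 5,
                                                                 id = "x"))),
               "different targets")
})
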