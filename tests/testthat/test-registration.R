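test_that("bone mask captures the skull shell", {
  ph <- clean_phantom()
  m <- bone_mask(ph$ct)
  expect_true(all(m[ph$skull]))       # dilated mask contains the shell
  expect_error(bone_mask(ph$ct, 1500), "empty")
  expect_error(bone_mask(derive_mr(ph$ct)), "CT")

  # undilated threshold volume vs analytic shell volume on a 1 mm grid
  spec1 <- phantom_spec(skull_outer_radii = c(50, 55, 45), skull_thickness = 6,
                        targets = list(target(c(10, 0, 0), 5)),
                        dims = c(116L, 126L, 106L), spacing = c(1, 1, 1),
                        antialias = 1L)
  ph1 <- make_head_phantom(spec1)
  m1 <- bone_mask(ph1$ct, dilate = 0L)
  outer_v <- prod(spec1$skull_outer_radii)
  inner_v <- prod(spec1$skull_outer_radii - spec1$skull_thickness)
  shell <- 4 / 3 * pi * (outer_v - inner_v)
  expect_lt(abs(sum(m1) * 1 - shell) / shell, 0.1)
})

test_that("self-registration returns the exact identity", {
  ph <- noisy_phantom()
  r <- register_rigid(ph$ct, ph$ct)
  expect_true(is_identity_transform(r$transform, 0.05, 0.05))
  expect_equal(r$final_similarity$mi, 1)
  rb <- register_rigid(ph$ct, ph$ct, "bone")
  expect_true(is_identity_transform(rb$transform, 0.05, 0.05))
})

test_that("CT-CT registration recovers known rigid motions to sub-voxel", {
  ph <- noisy_phantom()
  ctr <- image_center(ph$ct)
  set.seed(31)
  errs <- replicate(4, {
    tr <- runif(3, -5, 5); ro <- runif(3, -3, 3)
    Tt <- rigid_transform(tr[1], tr[2], tr[3], ro[1], ro[2], ro[3],
                          center = ctr)
    mov <- simulate_rescan(ph, Tt, noise_sigma = 3,
                           seed = sample.int(1e6, 1))
    rr <- register_rigid(mov, ph$ct)
    e <- transform_error(rr$transform, Tt)
    c(e$t_mm, e$rot_deg)
  })
  expect_lt(stats::median(errs[1, ]), 0.3)
  expect_lt(stats::median(errs[2, ]), 0.3)
})

test_that("bone-mode registration aligns the MR to a moved CT", {
  ph <- noisy_phantom()
  ctr <- image_center(ph$ct)
  mr <- derive_mr(ph$ct)
  Tt <- rigid_transform(3, -2, 1, 1, -1, 1.5, center = ctr)
  mov_ct <- simulate_rescan(ph, Tt, noise_sigma = 3, seed = 77)
  rb <- register_rigid(mr, mov_ct, "bone")
  # ground truth: the MR (aligned with the unmoved phantom) maps to the
  # moved CT under Tt itself
  e <- transform_error(rb$transform, invert_transform(Tt))
  expect_lt(e$t_mm, 0.6)
})

test_that("registration is invariant to affine intensity rescaling", {
  ph <- noisy_phantom()
  Tt <- rigid_transform(2, 1, -1.5, 1, 0.5, -1, center = image_center(ph$ct))
  mov <- simulate_rescan(ph, Tt, noise_sigma = 3, seed = 13)
  r1 <- register_rigid(mov, ph$ct)
  scaled <- mov
  scaled$voxels <- 0.5 * mov$voxels + 200
  r2 <- register_rigid(scaled, ph$ct)
  expect_equal(srsrescan:::transform_params(r1$transform),
               srsrescan:::transform_params(r2$transform), tolerance = 1e-6)
})

test_that("registration fails loudly without field-of-view overlap", {
  ph <- clean_phantom()
  expect_error(register_rigid(ph$ct, ph$ct,
                              init = rigid_transform(tx = 1e4)),
               "overlap")
})

test_that("the residual chain closes for consistent registrations", {
  ctr <- c(0, 0, 0)
  T_b <- rigid_transform(1.5, -2, 0.5, 1, -0.5, 2, center = ctr)  # rMR->iCT
  T_c <- rigid_transform(-0.5, 1, 2, -1, 1.5, 0.5, center = ctr)  # iCT->rCT
  T_a <- compose_transform(T_c, T_b)                              # consistent
  r0 <- residual_chain(T_a, T_b, T_c)
  expect_equal(r0$magnitude, 0, tolerance = 1e-9)
  expect_equal(c(r0$roll, r0$pitch, r0$yaw), c(0, 0, 0), tolerance = 1e-9)

  # a deliberate 1 mm discrepancy in the direct route
  r1 <- residual_chain(rigid_transform(1, 0, 0, center = ctr),
                       rigid_transform(center = ctr),
                       rigid_transform(center = ctr))
  expect_equal(r1$magnitude, 1, tolerance = 1e-12)

  # pure rotation discrepancy about the shared center: no translation there
  r2 <- residual_chain(rigid_transform(center = ctr),
                       rigid_transform(roll = 1, center = ctr),
                       rigid_transform(center = ctr))
  expect_equal(r2$roll, 1, tolerance = 1e-9)
  expect_equal(r2$magnitude, 0, tolerance = 1e-9)

  # magnitude is the Euclidean norm of the translation components
  expect_equal(r1$magnitude, sqrt(r1$tx^2 + r1$ty^2 + r1$tz^2))
  expect_error(residual_chain(rigid_transform(center = c(1, 1, 1)),
                              rigid_transform(center = ctr),
                              rigid_transform(center = ctr)),
               "center")
})
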