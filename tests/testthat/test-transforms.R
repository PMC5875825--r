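test_that("rigid transforms are isometries and compose/invert as a group", {
  set.seed(1)
  pts <- matrix(runif(30, -80, 80), ncol = 3)
  for (i in 1:10) {
    p <- c(runif(3, -5, 5), runif(3, -30, 30))
    Tr <- rigid_transform(p[1], p[2], p[3], p[4], p[5], p[6],
                          center = runif(3, -20, 20))
    q <- transform_points(Tr, pts)
    expect_lt(max(abs(dist(q) - dist(pts))) / max(dist(pts)), 1e-9)

    # two-sided inverse
    rt <- compose_transform(Tr, invert_transform(Tr))
    expect_true(is_identity_transform(rt, 1e-9, 1e-9))
    lf <- compose_transform(invert_transform(Tr), Tr)
    expect_true(is_identity_transform(lf, 1e-9, 1e-9))

    # round trip through the matrix decomposition
    back <- srsrescan:::transform_from_affine(rotation_matrix(Tr),
                                              srsrescan:::transform_affine(Tr)[, 4],
                                              Tr$center)
    expect_equal(srsrescan:::transform_params(back),
                 srsrescan:::transform_params(Tr), tolerance = 1e-6)
  }
})

test_that("compose matches sequential application and known cases", {
  A <- rigid_transform(1, 0, 0)
  B <- rigid_transform(0, 2, 0)
  AB <- compose_transform(A, B)
  expect_equal(c(AB$tx, AB$ty, AB$tz), c(1, 2, 0))
  expect_equal(c(AB$roll, AB$pitch, AB$yaw), c(0, 0, 0))

  expect_true(is_identity_transform(
    compose_transform(rigid_transform(), rigid_transform())))
  expect_true(is_identity_transform(
    compose_transform(rigid_transform(roll = 90), rigid_transform(roll = -90)),
    1e-9, 1e-9))

  # compose(A, B)(p) = A(B(p)) on random transforms and points
  set.seed(2)
  for (i in 1:5) {
    A <- rigid_transform(runif(1,-3,3), runif(1,-3,3), runif(1,-3,3),
                         runif(1,-20,20), runif(1,-20,20), runif(1,-20,20))
    B <- rigid_transform(runif(1,-3,3), runif(1,-3,3), runif(1,-3,3),
                         runif(1,-20,20), runif(1,-20,20), runif(1,-20,20))
    p <- matrix(runif(9, -50, 50), ncol = 3)
    expect_equal(transform_points(compose_transform(A, B), p),
                 transform_points(A, transform_points(B, p)),
                 tolerance = 1e-9)
  }

  # associativity
  C <- rigid_transform(0.5, -1, 2, 5, -3, 8)
  lhs <- compose_transform(compose_transform(A, B), C)
  rhs <- compose_transform(A, compose_transform(B, C))
  expect_equal(srsrescan:::transform_params(lhs),
               srsrescan:::transform_params(rhs), tolerance = 1e-9)

  expect_error(compose_transform(rigid_transform(center = c(1, 0, 0)),
                                 rigid_transform(center = c(0, 0, 0))),
               "center")
})

test_that("invert handles translations and rotation round trips", {
  Ti <- invert_transform(rigid_transform(3, -2, 1))
  expect_equal(c(Ti$tx, Ti$ty, Ti$tz), c(-3, 2, -1))
  expect_true(is_identity_transform(invert_transform(rigid_transform())))

  Ty <- rigid_transform(yaw = 30)
  p <- c(10, 0, 0)
  expect_equal(as.numeric(transform_points(invert_transform(Ty),
                                           transform_points(Ty, p))),
               p, tolerance = 1e-9)
})

test_that("recentering preserves the point mapping", {
  Tr <- rigid_transform(2, -1, 3, 10, -5, 7, center = c(5, 5, 5))
  T2 <- recenter_transform(Tr, c(-10, 0, 20))
  p <- matrix(runif(15, -40, 40), ncol = 3)
  expect_equal(transform_points(Tr, p), transform_points(T2, p),
               tolerance = 1e-9)
  expect_equal(T2$center, c(-10, 0, 20))
})

test_that("roll, pitch and yaw act about the stated anatomical axes", {
  # roll: about z (superior-inferior); +x rotates toward +y for +90 deg
  expect_equal(as.numeric(transform_points(rigid_transform(roll = 90),
                                           c(1, 0, 0))),
               c(0, 1, 0), tolerance = 1e-12)
  # pitch: about x (left-right); z stays fixed on the x axis
  expect_equal(as.numeric(transform_points(rigid_transform(pitch = 90),
                                           c(1, 0, 0))),
               c(1, 0, 0), tolerance = 1e-12)
  # yaw: about y (anterior-posterior)
  expect_equal(as.numeric(transform_points(rigid_transform(yaw = 90),
                                           c(0, 1, 0))),
               c(0, 1, 0), tolerance = 1e-12)
})
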