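test_that("quaternion algebra round-trips", {
  set.seed(1)
  for (i in 1:20) {
    q <- quat_normalize(rnorm(4))
    expect_equal(quat_to_rotmat(q), quat_to_rotmat(rotmat_to_quat(quat_to_rotmat(q))),
                 tolerance = 1e-10)
    v <- rnorm(3)
    expect_equal(quat_exp_map(quat_log_map(quat_exp_map(v * 0.3))),
                 quat_exp_map(v * 0.3), tolerance = 1e-10)
    # rotation action agrees with the matrix
    x <- rnorm(3)
    expect_equal(quat_rotate(q, x), as.numeric(quat_to_rotmat(q) %*% x),
                 tolerance = 1e-12)
  }
})

test_that("slerp interpolates at constant angular velocity", {
  q1 <- quat_identity()
  q2 <- quat_exp_map(c(0, 0, 60 * pi / 180))
  qh <- quat_slerp(q1, q2, 0.5)
  expect_equal(quat_log_map(qh), c(0, 0, 30 * pi / 180), tolerance = 1e-12)
  expect_equal(quat_slerp(q1, q2, 0), q1, tolerance = 1e-12)
  expect_equal(abs(sum(quat_slerp(q1, q2, 1) * q2)), 1, tolerance = 1e-12)
})

test_that("pose composition and inverse are consistent", {
  set.seed(2)
  for (i in 1:10) {
    p1 <- pose(rnorm(3), quat_normalize(rnorm(4)))
    p2 <- pose(rnorm(3), quat_normalize(rnorm(4)))
    x <- rnorm(3)
    expect_equal(pose_apply(pose_compose(p1, p2), x),
                 pose_apply(p1, pose_apply(p2, x)), tolerance = 1e-10)
    ident <- pose_compose(p1, pose_inverse(p1))
    expect_equal(ident$t, c(0, 0, 0), tolerance = 1e-10)
    expect_equal(abs(ident$q[1]), 1, tolerance = 1e-10)
  }
})
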