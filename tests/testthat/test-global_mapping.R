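test_that("the rotation-constrained Jacobian follows the closed form", {
  set.seed(30)
  # identity case: full information ratios leave the Jacobian unchanged
  J <- matrix(rnorm(15), ncol = 3)
  expect_equal(constrain_rotation_jacobian(J, diag(3), 1, 1), J, tolerance = 1e-12)
  # vanishing ratios keep only the z column
  Jc <- constrain_rotation_jacobian(diag(3), diag(3), 1e-9, 1e-9)
  expect_lt(max(abs(Jc[, 1:2])), 1e-8)
  expect_equal(Jc[, 3], c(0, 0, 1), tolerance = 1e-12)
  # random inputs match the explicit three-matrix product
  for (i in 1:10) {
    J <- matrix(rnorm(18), ncol = 3)
    R <- quat_to_rotmat(quat_normalize(rnorm(4)))
    ex <- runif(1, 0.05, 1); ey <- runif(1, 0.05, 1)
    expect_equal(constrain_rotation_jacobian(J, R, ex, ey),
                 J %*% t(R) %*% diag(c(ex, ey, 1)), tolerance = 1e-12)
  }
  expect_error(constrain_rotation_jacobian(diag(3), diag(3), 0, 0.5), "\\(0, 1\\]")
  expect_error(constrain_rotation_jacobian(diag(3), 2 * diag(3), 0.5, 0.5),
               "orthonormal")
})

# a box-corner map: floor plus two walls, fully constraining all 6 DoF
box_map <- function(step = 0.1) {
  g <- as.matrix(expand.grid(u = seq(-4, 4, step), v = seq(-4, 4, step)))
  rbind(cbind(g, 0), cbind(g[, 1], 4.2, g[, 2] + 4), cbind(4.2, g[, 1], g[, 2] + 4))
}

test_that("map registration recovers a perturbed pose on synthetic planes", {
  set.seed(31)
  mp <- box_map()
  truth <- pose()
  feats <- list(planar = mp[sample(nrow(mp), 400), ])
  # features exactly on the map at the true pose: nothing moves
  reg0 <- register_to_map(feats, truth, list(planar = mp), constrained = FALSE,
                          meas_sigma = 0.02)
  expect_lt(pos_error(reg0$pose, truth), 1e-9)
  expect_lt(reg0$cost, 1e-9)

  # perturbed init recovered to millimetres
  init <- pose(c(0.15, -0.12, 0.1), quat_exp_map(c(0.02, -0.015, 0.025)))
  reg <- register_to_map(feats, init, list(planar = mp), constrained = FALSE,
                         meas_sigma = 0.005, corr_radius = 1.5)
  expect_lt(pos_error(reg$pose, truth), 1e-3)
  expect_lt(rot_error_deg(reg$pose, truth), 0.02)

  # empty map passes the initial pose through with a warning
  expect_warning(regE <- register_to_map(feats, init, list(planar = mp[0, , drop = FALSE])),
                 "empty")
  expect_equal(regE$pose$t, init$t)
})

test_that("map assembly voxelises correctly", {
  set.seed(32)
  sweep1 <- matrix(runif(3000, 0, 2), ncol = 3)
  # one sweep at identity: map equals the sweep, downsampled
  m1 <- assemble_map(list(sweep1), list(pose()), voxel_size = 0.05)
  expect_lte(nrow(m1$points), nrow(sweep1))
  # two identical sweeps: same occupied voxels as one
  m2 <- assemble_map(list(sweep1, sweep1), list(pose(), pose()), voxel_size = 0.05)
  expect_equal(nrow(m2$points), nrow(m1$points))
  expect_equal(m2$points, m1$points, tolerance = 1e-12)
  # centroids match a brute-force grid binning
  pts <- matrix(runif(3000, 0, 1), ncol = 3)
  m3 <- assemble_map(list(pts), list(pose()), voxel_size = 0.2)
  key <- apply(floor(sweep(pts, 2, apply(pts, 2, min)) / 0.2), 1, paste, collapse = "/")
  brute <- do.call(rbind, lapply(split(seq_len(nrow(pts)), key), function(i)
    colMeans(pts[i, , drop = FALSE])))
  ord1 <- order(m3$points[, 1], m3$points[, 2], m3$points[, 3])
  ord2 <- order(brute[, 1], brute[, 2], brute[, 3])
  expect_equal(unname(m3$points[ord1, ]), unname(brute[ord2, ]), tolerance = 1e-12)
  expect_error(assemble_map(list(pts), list(pose(), pose())), "one pose per sweep")
})

test_that("sensor-height ground removal partitions the cloud", {
  # threshold arithmetic at d = 0.8: z < -0.6 is ground
  cloud <- data.frame(x = 0, y = 0, z = c(-0.7, -0.5))
  sp <- remove_ground_by_sensor_height(cloud, 0.8)
  expect_equal(sp$ground$z, -0.7)
  expect_equal(sp$nonground$z, -0.5)
  expect_error(remove_ground_by_sensor_height(cloud, -1), "positive")
  # empty cloud -> two empty parts
  sp0 <- remove_ground_by_sensor_height(cloud[0, ], 0.8)
  expect_equal(nrow(sp0$ground) + nrow(sp0$nonground), 0)
  # synthetic scene at the default mount height
  sc <- generate_scene(2, 4, overlap_fraction = 0, seed = 33)
  cl <- sample_scene_points(sc, density = 400, sigma = 0.02, seed = 34)
  sp2 <- remove_ground_by_sensor_height(cl, 0.8)
  expect_gte(sum(sp2$ground$label == 0) / sum(cl$label == 0), 0.99)
  expect_lt(sum(sp2$ground$label > 0) / sum(cl$label > 0), 0.01)
  # partition: union = input, intersection = empty
  expect_equal(nrow(sp2$ground) + nrow(sp2$nonground), nrow(cl))
})

test_that("the rotation constraint suppresses terminal z drift", {
  # scaled-down paired ablation (the acceptance suite runs the full one)
  rc <- run_mapping_ablation(seed = 301, constrained = TRUE, n_frames = 40)
  ru <- run_mapping_ablation(seed = 301, constrained = FALSE, n_frames = 40)
  expect_lte(rc$z_drift, ru$z_drift)
})
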