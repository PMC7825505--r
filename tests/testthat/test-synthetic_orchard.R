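test_that("generate_scene honours the orchard lattice and is deterministic", {
  sc1 <- generate_scene(1, 1, overlap_fraction = 0, seed = 7)
  expect_equal(nrow(sc1$trees), 1)

  sc <- generate_scene(7, 10, overlap_fraction = 0.2, seed = 1)
  expect_equal(nrow(sc$trees), 70)
  expect_equal(sc$row_spacing, 5)
  expect_equal(sc$in_row_spacing, 4)
  # centres on the lattice up to the stated jitter
  offx <- sc$trees$cx - (sc$trees$col - 1) * 4
  offy <- sc$trees$cy - (sc$trees$row - 1) * 5
  expect_lt(max(abs(offy)), 0.5)
  expect_lt(max(abs(offx)), 0.5)
  expect_true(all(sc$trees$x > 0 & sc$trees$y > 0 & sc$trees$base_height >= 0))

  sc2 <- generate_scene(7, 10, overlap_fraction = 0.2, seed = 1)
  expect_identical(sc, sc2)

  expect_error(generate_scene(0, 5, seed = 1), "positive")
  expect_error(generate_scene(2, 2, overlap_fraction = 1.5, seed = 1), "\\[0, 1\\]")
})

test_that("overlap pairs bring the two canopies within the clustering radius", {
  sc <- generate_scene(1, 2, overlap_fraction = 1, seed = 3)
  expect_equal(nrow(sc$overlap_pairs), 1)
  cl <- segmentation_cloud(sc, seed = 4)
  a <- as.matrix(cl[cl$label == 1, c("x", "y", "z")])
  b <- as.matrix(cl[cl$label == 2, c("x", "y", "z")])
  nn <- orchardcanopy:::cpp_knn(b, a, k = 1)
  expect_lt(min(nn$dist), 0.02)
})

test_that("sampled points respect the scene geometry and labels partition", {
  sc <- single_tree_scene(shape = "ellipsoid", x = 2, y = 2, base = 0.5)
  cl <- sample_scene_points(sc, density = 500, sigma = 0, seed = 5,
                            ground_density = 50, interior_fraction = 0)
  expect_true(all(cl$label %in% c(0, 1)))
  crown <- cl[cl$label == 1, ]
  # noise-free surface points satisfy the implicit ellipsoid equation
  impl <- ((crown$x - sc$trees$cx) / 1)^2 + ((crown$y - sc$trees$cy) / 1)^2 +
    ((crown$z + sc$sensor_height - sc$trees$base_height - 1) / 1)^2
  expect_lt(max(abs(impl - 1)), 1e-9)
  # ground points lie on the plane
  expect_lt(max(abs(cl$z[cl$label == 0] + sc$sensor_height)), 1e-12)

  # count oracle on a sphere (x = y) with exactly known area
  n_crown <- sum(cl$label == 1)
  expect_lt(abs(n_crown / (500 * 4 * pi) - 1), 0.05)

  # ground-only scene has only ground labels
  g <- sample_scene_points(ground_only_scene(), density = 100, sigma = 0,
                           seed = 6, ground_density = 30)
  expect_true(all(g$label == 0))
})

test_that("simulated IMU matches the analytic kinematics", {
  sc <- generate_scene(3, 3, overlap_fraction = 0, seed = 8)
  sim <- simulate_trajectory(sc, speed = 1.5, seed = NULL,
                             imu = imu_model(gyro_noise = 0, accel_noise = 0),
                             static_time = 0.5, pitch_amp = 0, roll_amp = 0)
  imu <- sim$imu
  # constant-velocity straights: accelerometer reads -g in body frame, gyro 0
  tr <- sim$trajectory
  spd <- sqrt(diff(tr$tx)^2 + diff(tr$ty)^2) / diff(tr$timestamp)
  mask <- abs(spd - 1.5) < 1e-9 & abs(diff(tr$qz)) < 1e-12
  # erode the mask so segment-boundary samples (where speed has just
  # reached cruise but acceleration still acts) are excluded
  straight <- which(mask & c(FALSE, FALSE, mask[-(1:2)]) &
                    c(mask[-(1:2)], FALSE, FALSE))
  straight <- straight[straight > 5]
  expect_gt(length(straight), 100)
  expect_lt(max(abs(imu$az[straight] - 9.81)), 1e-9)
  expect_lt(max(abs(imu$ax[straight])), 1e-9)
  expect_lt(max(abs(imu$wz[straight])), 1e-9)
  # constant-rate arc turns: gyro z equals speed / radius
  sim2 <- simulate_trajectory(sc, speed = 1.5, seed = NULL,
                              imu = imu_model(gyro_noise = 0, accel_noise = 0),
                              static_time = 0.5, pitch_amp = 0, roll_amp = 0,
                              turn_style = "arc")
  arc <- which(abs(abs(sim2$imu$wz) - 1.5 / 2.5) < 1e-9)
  expect_gt(length(arc), 100)
})

test_that("integrating noise-free IMU recovers the trajectory", {
  sc <- generate_scene(3, 6, overlap_fraction = 0, seed = 9)
  sim <- simulate_trajectory(sc, speed = 1, seed = NULL,
                             imu = imu_model(gyro_noise = 0, accel_noise = 0),
                             static_time = 1)
  imu <- sim$imu; tr <- sim$trajectory
  n <- min(nrow(imu), 400 * 60 + 1)  # up to 60 s
  p <- c(tr$tx[1], tr$ty[1], tr$tz[1]); v <- c(0, 0, 0)
  q <- c(tr$qw[1], tr$qx[1], tr$qy[1], tr$qz[1])
  g <- c(0, 0, -9.81)
  W <- as.matrix(imu[, c("wx", "wy", "wz")])
  A <- as.matrix(imu[, c("ax", "ay", "az")])
  for (i in seq_len(n - 1)) {
    dt <- imu$timestamp[i + 1] - imu$timestamp[i]
    w <- 0.5 * (W[i, ] + W[i + 1, ])
    R0 <- quat_to_rotmat(q)
    q <- quat_normalize(quat_multiply(q, quat_exp_map(w * dt)))
    R1 <- quat_to_rotmat(q)
    aw <- 0.5 * (R0 %*% A[i, ] + R1 %*% A[i + 1, ]) + g
    p <- p + v * dt + 0.5 * as.numeric(aw) * dt^2
    v <- v + as.numeric(aw) * dt
  }
  expect_lt(sqrt(sum((p - c(tr$tx[n], tr$ty[n], tr$tz[n]))^2)), 1e-3)
})

test_that("ray casting hits analytic surfaces exactly", {
  # sensor 1 m above an infinite ground plane, no noise: the -15 degree beam
  # returns 1 / sin(15 deg)
  sc <- ground_only_scene(sensor_height = 1)
  lid <- lidar_model(range_sigma = 0)
  scan <- simulate_scan(sc, pose(), lid, seed = NULL)
  r0 <- scan$range[scan$ring == 0]
  expect_equal(unique(round(r0, 9)), round(1 / sin(15 * pi / 180), 9))

  # empty scene: no ground, no trees -> no returns
  sc2 <- ground_only_scene()
  sc2$ground <- c(0, 0, 1, 1e6)  # plane far below everything
  scan2 <- simulate_scan(sc2, pose(), lid, seed = NULL)
  expect_true(all(scan2$range > 1000) || nrow(scan2) == 0)

  # sphere of radius 1 centred 5 m ahead: the horizontal forward ray
  # returns 4 m
  sc3 <- single_tree_scene(shape = "ellipsoid", x = 2, y = 2,
                           base = 1, cx = 5, cy = 0, sensor_height = 2)
  lid3 <- lidar_model(n_beams = 3, vertical_fov = 15, range_sigma = 0)
  scan3 <- simulate_scan(sc3, pose(), lid3, seed = NULL)
  fwd <- scan3[scan3$ring == 1 & abs(scan3$y) < 0.01 & scan3$x > 0, ]
  expect_gt(nrow(fwd), 0)
  expect_lt(abs(min(fwd$range) - 4), 2e-3)

  # determinism under a fixed seed
  s1 <- simulate_scan(sc3, pose(), lidar_model(), seed = 11)
  s2 <- simulate_scan(sc3, pose(), lidar_model(), seed = 11)
  expect_identical(s1, s2)
})
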