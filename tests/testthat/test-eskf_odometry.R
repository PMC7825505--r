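imu_rows <- function(ts, w, a) {
  data.frame(timestamp = ts,
             wx = w[1], wy = w[2], wz = w[3],
             ax = a[1], ay = a[2], az = a[3])
}

test_that("propagation is at equilibrium for a stationary, bias-free stream", {
  st <- eskf_state(g = c(0, 0, -9.81))
  P <- eskf_initial_covariance()
  imu <- imu_rows(seq(0, 0.1, by = 0.0025), c(0, 0, 0), c(0, 0, 9.81))
  out <- eskf_propagate(st, P, imu)
  expect_equal(out$state$p, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(out$state$v, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(out$state$q, quat_identity(), tolerance = 1e-12)
  # covariance trace grows when Q != 0
  expect_gt(sum(diag(out$P)), sum(diag(P)))
  # with zero process noise only the deterministic transition acts: the
  # trace stays strictly below the noisy propagation's
  out0 <- eskf_propagate(st, P, imu, noise = list(gyro = 0, accel = 0,
                                                  gyro_rw = 0, accel_rw = 0))
  expect_lt(sum(diag(out0$P)), sum(diag(out$P)))
  expect_lt(max(abs(out0$P - t(out0$P))), 1e-15)

  expect_error(eskf_propagate(st, P, imu[0, ]), "empty")
  bad <- imu; bad$timestamp[3] <- bad$timestamp[2]
  expect_error(eskf_propagate(st, P, bad), "strictly increasing")
})

test_that("constant acceleration integrates to the closed form", {
  st <- eskf_state(g = c(0, 0, -9.81))
  P <- eskf_initial_covariance()
  a <- 2.5
  imu <- imu_rows(seq(0, 0.1, by = 0.0025), c(0, 0, 0), c(a, 0, 9.81))
  out <- eskf_propagate(st, P, imu)
  expect_equal(out$state$p, c(0.5 * a * 0.1^2, 0, 0), tolerance = 1e-6)
  expect_equal(out$state$v, c(a * 0.1, 0, 0), tolerance = 1e-9)
})

test_that("covariance stays symmetric positive semi-definite through propagation", {
  set.seed(20)
  st <- eskf_state(g = c(0, 0, -9.81))
  P <- eskf_initial_covariance()
  for (rep in 1:5) {
    w <- rnorm(3, 0, 0.2); a <- rnorm(3, 0, 1) + c(0, 0, 9.81)
    imu <- imu_rows(seq(0, 0.1, by = 0.0025), w, a)
    out <- eskf_propagate(st, P, imu)
    st <- out$state; P <- out$P
    expect_lt(max(abs(P - t(P))), 1e-12)
    expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  }
})

test_that("residual Jacobians match central finite differences", {
  set.seed(21)
  for (rep in 1:5) {
    ref <- list(edge = matrix(rnorm(30, sd = 2), ncol = 3),
                planar = matrix(rnorm(45, sd = 2), ncol = 3))
    feats <- list(edge = ref$edge[1:5, ] + rnorm(15, 0, 0.05),
                  planar = ref$planar[1:8, ] + rnorm(24, 0, 0.05))
    st <- eskf_state(p = rnorm(3, 0, 0.02), q = quat_exp_map(rnorm(3, 0, 0.02)))
    rs <- build_residuals(feats, ref, pose(st$p, st$q), corr_radius = 10)
    expect_false(is.null(rs))
    eps <- 1e-6
    for (d in c(1:3, 7:9)) {
      dx <- rep(0, 18); dx[d] <- eps
      stp <- eskf_inject(st, dx); stm <- eskf_inject(st, -dx)
      fp <- build_residuals(feats, ref, pose(stp$p, stp$q), corr_radius = 10)$f
      fm <- build_residuals(feats, ref, pose(stm$p, stm$q), corr_radius = 10)$f
      fd <- (fp - fm) / (2 * eps)
      expect_lt(max(abs(fd - rs$H[, d])), 1e-5)
    }
  }
})

test_that("residual geometry is exact on constructed cases", {
  # perfectly aligned features give a zero residual vector
  ref <- list(edge = matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE),
              planar = matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), ncol = 3, byrow = TRUE))
  feats <- list(edge = matrix(c(0.5, 0, 0), ncol = 3),
                planar = matrix(c(0.3, 0.3, 0), ncol = 3))
  rs <- build_residuals(feats, ref, pose())
  expect_lt(max(abs(rs$f)), 1e-12)

  # a planar point 0.1 m off a known plane has residual 0.1
  feats2 <- list(planar = matrix(c(0.3, 0.3, 0.1), ncol = 3))
  rs2 <- build_residuals(feats2, ref, pose())
  expect_equal(abs(rs2$f), 0.1, tolerance = 1e-12)

  # no valid correspondences -> NULL (caller falls back to the prior)
  far <- list(planar = matrix(c(50, 50, 50), ncol = 3))
  expect_null(build_residuals(far, ref, pose(), corr_radius = 1))
})

test_that("the iterated update recovers a known relative motion", {
  set.seed(22)
  # reference: a dense flat patch plus two crossing edge lines
  gx <- as.matrix(expand.grid(x = seq(-3, 3, 0.15), y = seq(-3, 3, 0.15)))
  ref_planar <- cbind(gx, 0)
  tline <- seq(-2, 2, 0.05)
  ref_edge <- rbind(cbind(tline, 0.5, 0.3 + tline * 0), cbind(0.8, tline, 1))
  truth <- pose(c(0.5, 0, 0), quat_exp_map(c(0, 0, 2 * pi / 180)))
  inv <- pose_inverse(truth)
  feats <- list(planar = pose_apply(inv, ref_planar[sample(nrow(ref_planar), 300), ]),
                edge = pose_apply(inv, ref_edge))
  st <- eskf_state()  # prior at identity, 0.5 m / 2 deg away from the truth
  P <- eskf_initial_covariance(pos_sd = 1, vel_sd = 0.1, ang_sd = 0.5)
  up <- eskf_iterated_update(st, P, feats, list(edge = ref_edge, planar = ref_planar),
                             meas_sigma = 0.01, corr_radius = 2, max_iter = 10)
  got <- pose(up$state$p, up$state$q)
  expect_lt(pos_error(got, truth), 1e-3)
  expect_lt(rot_error_deg(got, truth), 0.01)
  # the MAP objective is non-increasing over accepted iterations
  expect_true(all(diff(up$objective) <= 1e-9))
  # posterior covariance stays symmetric PSD
  expect_lt(max(abs(up$P - t(up$P))), 1e-10)
  expect_gt(min(eigen(up$P, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
})

test_that("uninformative measurements leave the prior untouched", {
  ref <- list(planar = matrix(rnorm(60), ncol = 3))
  feats <- list(planar = ref$planar[1:5, ])
  st <- eskf_state(p = c(0.1, 0, 0))
  P <- eskf_initial_covariance()
  up <- eskf_iterated_update(st, P, feats, ref, meas_sigma = 1e4, corr_radius = 10)
  expect_lt(sqrt(sum((up$state$p - st$p)^2)), 1e-4)
})

test_that("static initialization estimates gravity and gyro bias", {
  set.seed(23)
  n <- 400
  bg <- c(0.01, -0.02, 0.005)
  imu <- data.frame(timestamp = seq(0, 1, length.out = n),
                    wx = bg[1] + rnorm(n, 0, 1e-3),
                    wy = bg[2] + rnorm(n, 0, 1e-3),
                    wz = bg[3] + rnorm(n, 0, 1e-3),
                    ax = rnorm(n, 0, 1e-3), ay = rnorm(n, 0, 1e-3),
                    az = 9.81 + rnorm(n, 0, 1e-3))
  st <- eskf_static_init(imu)
  expect_lt(max(abs(st$g - c(0, 0, -9.81))), 1e-3)
  expect_lt(max(abs(st$bg - bg)), 5e-4)
  moving <- imu; moving$ax <- moving$ax + sin(seq(0, 20, length.out = n))
  expect_error(eskf_static_init(moving), "motion detected")
})

test_that("odometry holds still on a stationary sequence and is deterministic", {
  sc <- generate_scene(2, 3, overlap_fraction = 0, seed = 24)
  lid <- lidar_model(range_sigma = 0)
  sim <- simulate_trajectory(sc, speed = 1, seed = 25, static_time = 3)
  times <- seq(1, 2.5, by = 0.1)  # still inside the static dwell
  scans <- simulate_sweep_sequence(sc, sim$trajectory, lid, times = times, seed = 26)
  # scans are noise-free and the platform is static, so the residual error
  # budget is essentially zero and the LiDAR can pin the IMU's noise drift
  od1 <- run_odometry(scans, sim$imu, lid, config = list(meas_sigma = 0.001))
  last <- od1$trajectory[nrow(od1$trajectory), ]
  expect_lt(sqrt(last$tx^2 + last$ty^2 + last$tz^2), 1e-3)
  od2 <- run_odometry(scans, sim$imu, lid, config = list(meas_sigma = 0.001))
  expect_identical(od1$trajectory, od2$trajectory)
})
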