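#' Error-state Kalman filter state
#'
#' The nominal state of the LiDAR-inertial odometry:
#' translation `p` (m), velocity `v` (m/s), attitude quaternion `q`,
#' accelerometer bias `ba` (m/s^2), gyroscope bias `bg` (rad/s) and the
#' gravity vector `g` (m/s^2), all expressed in the reference frame of the
#' current sweep interval. The companion error state
#' `dx = [dp, dv, dtheta, dba, dbg, dg]` is an 18-vector with covariance
#' `P` (18 x 18); `dtheta` is a small rotation vector injected on the right
#' of `q`.
#'
#' @param p,v,ba,bg,g length-3 numerics.
#' @param q unit quaternion `(w, x, y, z)`.
#' @export
eskf_state <- function(p = c(0, 0, 0), v = c(0, 0, 0), q = quat_identity(),
                       ba = c(0, 0, 0), bg = c(0, 0, 0), g = c(0, 0, -9.81)) {
  structure(list(p = as.numeric(p), v = as.numeric(v), q = quat_normalize(q),
                 ba = as.numeric(ba), bg = as.numeric(bg), g = as.numeric(g)),
            class = "eskf_state")
}

# error-state block indices
ESKF_IP <- 1:3; ESKF_IV <- 4:6; ESKF_ITH <- 7:9
ESKF_IBA <- 10:12; ESKF_IBG <- 13:15; ESKF_IG <- 16:18

#' @rdname eskf_state
#' @param pos_sd,vel_sd,ang_sd,ba_sd,bg_sd,g_sd initial 1-sigma
#'   uncertainties for the respective error blocks. The relative pose at
#'   the start of a sweep interval is identically zero, so its blocks
#'   start (numerically) at zero and grow only through IMU process noise.
#' @export
eskf_initial_covariance <- function(pos_sd = 1e-6, vel_sd = 1e-3, ang_sd = 1e-6,
                                    ba_sd = 1e-2, bg_sd = 1e-3, g_sd = 1e-2) {
  diag(rep(c(pos_sd, vel_sd, ang_sd, ba_sd, bg_sd, g_sd)^2, each = 3))
}

#' Inject an error vector into the nominal state
#'
#' Additive for the vector blocks; the attitude gets the quaternion product
#' with `exp(dtheta)` on the right.
#'
#' @param state an [eskf_state()].
#' @param dx length-18 error vector.
#' @export
eskf_inject <- function(state, dx) {
  eskf_state(p = state$p + dx[ESKF_IP],
             v = state$v + dx[ESKF_IV],
             q = quat_normalize(quat_multiply(state$q, quat_exp_map(dx[ESKF_ITH]))),
             ba = state$ba + dx[ESKF_IBA],
             bg = state$bg + dx[ESKF_IBG],
             g = state$g + dx[ESKF_IG])
}

#' IMU propagation of the nominal state and error covariance
#'
#' Integrates the nominal state sample-to-sample with bias-corrected
#' measurements (midpoint quaternion integration, trapezoidal specific
#' force) and propagates the error covariance with the first-order discrete
#' transition `P <- (I + F dt) P (I + F dt)' + (G dt) Q (G dt)'` per sample
#' pair. The error model is the standard continuous-time ESKF
#' linearization: position errors grow with velocity errors, velocity
#' errors with attitude/accelerometer-bias/gravity errors, attitude errors
#' with gyro-bias errors.
#'
#' @param state an [eskf_state()].
#' @param P 18 x 18 error covariance.
#' @param imu_batch IMU samples (`timestamp, wx..az`) spanning the interval;
#'   timestamps must be ordered.
#' @param noise list with per-sample standard deviations `gyro`, `accel`
#'   and bias random-walk densities `gyro_rw`, `accel_rw`.
#' @return list with the propagated `state` and `P`.
#' @export
eskf_propagate <- function(state, P, imu_batch,
                           noise = list(gyro = 0.003, accel = 0.012,
                                        gyro_rw = 1e-5, accel_rw = 1e-4)) {
  n <- nrow(imu_batch)
  if (is.null(n) || n == 0) stop("empty IMU batch")
  if (n > 1 && any(diff(imu_batch$timestamp) <= 0))
    stop("IMU timestamps must be strictly increasing")
  if (n == 1) return(list(state = state, P = P))
  W <- as.matrix(imu_batch[, c("wx", "wy", "wz")])
  A <- as.matrix(imu_batch[, c("ax", "ay", "az")])
  ts <- imu_batch$timestamp
  Qd <- rep(c(noise$gyro, noise$accel, noise$gyro_rw, noise$accel_rw)^2, each = 3)
  for (i in seq_len(n - 1)) {
    dt <- ts[i + 1] - ts[i]
    w_mid <- unname(0.5 * (W[i, ] + W[i + 1, ]) - state$bg)
    a0 <- unname(A[i, ] - state$ba)
    a1 <- unname(A[i + 1, ] - state$ba)
    R0 <- quat_to_rotmat(state$q)
    q1 <- quat_normalize(quat_multiply(state$q, quat_exp_map(w_mid * dt)))
    R1 <- quat_to_rotmat(q1)
    a_w <- 0.5 * (as.numeric(R0 %*% a0) + as.numeric(R1 %*% a1)) + state$g
    state$p <- state$p + state$v * dt + 0.5 * a_w * dt^2
    state$v <- state$v + a_w * dt
    state$q <- q1
    # Phi = I + F dt
    Phi <- diag(18)
    Phi[ESKF_IP, ESKF_IV] <- diag(3) * dt
    Phi[ESKF_IV, ESKF_ITH] <- -R0 %*% skew3(a0) * dt
    Phi[ESKF_IV, ESKF_IBA] <- -R0 * dt
    Phi[ESKF_IV, ESKF_IG] <- diag(3) * dt
    Phi[ESKF_ITH, ESKF_ITH] <- diag(3) - skew3(w_mid) * dt
    Phi[ESKF_ITH, ESKF_IBG] <- -diag(3) * dt
    # G dt maps white noise [n_g, n_a, n_bg, n_ba] into the error state
    Gdt <- matrix(0, 18, 12)
    Gdt[ESKF_ITH, 1:3] <- -diag(3) * dt
    Gdt[ESKF_IV, 4:6] <- R0 * dt
    Gdt[ESKF_IBG, 7:9] <- diag(3) * dt
    Gdt[ESKF_IBA, 10:12] <- diag(3) * dt
    P <- Phi %*% P %*% t(Phi) + Gdt %*% (Qd * t(Gdt))
    P <- (P + t(P)) / 2
  }
  list(state = state, P = P)
}

#' Build LiDAR feature residuals against a reference feature set
#'
#' Each edge feature, transformed by the current pose estimate, is matched
#' to the line through its two nearest reference edge points
#' (point-to-line residual, a 3-vector linear in the transformed point);
#' each planar feature to the plane through its three nearest reference
#' planar points (point-to-plane distance). Matches farther than
#' `corr_radius` and degenerate sets (near-identical line points,
#' near-collinear plane points below `cond_thresh`) are dropped. `H` is the
#' analytic Jacobian of the stacked residual with respect to the 18-dim
#' error state (only the translation and attitude blocks are non-zero); the
#' noise Jacobian is the identity, so the measurement covariance is
#' `sigma^2 I`.
#'
#' @param features a `feature_set` (or list with `edge`/`planar` matrices)
#'   in the current body frame.
#' @param reference list with `edge` and `planar` point matrices in the
#'   target frame.
#' @param pose_ current estimate of the body-to-target transform ([pose()]).
#' @param corr_radius correspondence search radius, metres.
#' @param cond_thresh degeneracy threshold for plane normals.
#' @return list `(f, H, n_edge, n_plane)` or `NULL` when no valid
#'   correspondence exists (caller falls back to the IMU-only prior).
#' @export
build_residuals <- function(features, reference, pose_, corr_radius = 1,
                            cond_thresh = 1e-3) {
  R <- quat_to_rotmat(pose_$q)
  cur_e <- if (inherits(features, "feature_set")) feature_points(features, "edge") else as_xyz(features$edge %||% matrix(numeric(0), ncol = 3))
  cur_p <- if (inherits(features, "feature_set")) feature_points(features, "planar") else as_xyz(features$planar %||% matrix(numeric(0), ncol = 3))
  ref_e <- reference$edge
  ref_p <- reference$planar
  f_list <- list(); H_list <- list()
  n_edge <- 0L; n_plane <- 0L
  if (nrow(cur_e) > 0 && !is.null(ref_e) && nrow(ref_e) >= 2) {
    y <- sweep(cur_e %*% t(R), 2, pose_$t, "+")
    nn <- cpp_knn(ref_e, y, k = 2)
    for (i in seq_len(nrow(y))) {
      if (nn$dist[i, 2] > corr_radius) next
      a <- ref_e[nn$idx[i, 1], ]; b <- ref_e[nn$idx[i, 2], ]
      L <- sqrt(sum((a - b)^2))
      if (L < 1e-9) next
      Jy <- -skew3(a - b) / L
      r <- as.numeric(Jy %*% (y[i, ] - a))
      Hp <- Jy
      Hth <- Jy %*% (-R %*% skew3(cur_e[i, ]))
      Hrow <- matrix(0, 3, 18)
      Hrow[, ESKF_IP] <- Hp
      Hrow[, ESKF_ITH] <- Hth
      f_list[[length(f_list) + 1]] <- r
      H_list[[length(H_list) + 1]] <- Hrow
      n_edge <- n_edge + 1L
    }
  }
  if (nrow(cur_p) > 0 && !is.null(ref_p) && nrow(ref_p) >= 3) {
    y <- sweep(cur_p %*% t(R), 2, pose_$t, "+")
    nn <- cpp_knn(ref_p, y, k = 3)
    for (i in seq_len(nrow(y))) {
      if (nn$dist[i, 3] > corr_radius) next
      a <- ref_p[nn$idx[i, 1], ]; b <- ref_p[nn$idx[i, 2], ]; c_ <- ref_p[nn$idx[i, 3], ]
      u <- b - a; v <- c_ - a
      nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
      nn2 <- sqrt(sum(nrm^2))
      den <- sqrt(sum(u^2)) * sqrt(sum(v^2))
      if (den < 1e-12 || nn2 / den < cond_thresh) next
      nrm <- nrm / nn2
      s <- sum(nrm * y[i, ]) - sum(nrm * a)
      Hrow <- matrix(0, 1, 18)
      Hrow[, ESKF_IP] <- nrm
      Hrow[, ESKF_ITH] <- -t(nrm) %*% R %*% skew3(cur_p[i, ])
      f_list[[length(f_list) + 1]] <- s
      H_list[[length(H_list) + 1]] <- Hrow
      n_plane <- n_plane + 1L
    }
  }
  if (!length(f_list)) return(NULL)
  list(f = unlist(f_list), H = do.call(rbind, H_list),
       n_edge = n_edge, n_plane = n_plane)
}

#' Iterated measurement update
#'
#' Gauss-Newton iteration on the maximum-a-posteriori problem
#' `min_dx |dx|_P^-1 + |f(x (+) dx)|_M^-1`: residuals and Jacobians are
#' recomputed at the current estimate, the Kalman gain
#' `K = P H' (H P H' + M)^-1` maps them to a new error vector
#' `dx <- K (H dx - f)`, and iteration stops when the step norm falls below
#' `tol` or after `max_iter` rounds. The error is then injected into the
#' nominal state and the posterior covariance is formed in Joseph form
#' `(I - K H) P (I - K H)' + K M K'`, which preserves symmetry.
#'
#' @param state prior [eskf_state()] (body-to-reference transform in
#'   `p`, `q`).
#' @param P prior covariance (positive definite).
#' @param features,reference,corr_radius as in [build_residuals()].
#' @param meas_sigma measurement noise standard deviation, metres.
#' @param max_iter,tol inner-loop controls.
#' @return list `(state, P, iterations, objective, n_matches, updated)`.
#' @export
eskf_iterated_update <- function(state, P, features, reference,
                                 meas_sigma = 0.05, max_iter = 10, tol = 1e-6,
                                 corr_radius = 1) {
  Pinv <- tryCatch(solve(P), error = function(e) solve(P + diag(1e-12, 18)))
  dx <- rep(0, 18)
  obj_trace <- numeric()
  K <- NULL; H <- NULL
  objective <- function(dx, f) {
    as.numeric(t(dx) %*% Pinv %*% dx + sum(f^2) / meas_sigma^2)
  }
  resid_at <- function(dx) {
    st <- eskf_inject(state, dx)
    build_residuals(features, reference, pose(st$p, st$q), corr_radius)
  }
  rs <- resid_at(dx)
  if (is.null(rs)) {
    return(list(state = state, P = P, iterations = 0L,
                objective = numeric(), n_matches = 0L, updated = FALSE))
  }
  obj <- objective(dx, rs$f)
  for (j in seq_len(max_iter)) {
    H <- rs$H
    S <- H %*% P %*% t(H) + diag(meas_sigma^2, nrow(H))
    K <- P %*% t(H) %*% tryCatch(solve(S), error = function(e) {
      warning("singular innovation matrix; regularizing")
      solve(S + diag(1e-9, nrow(S)))
    })
    dx_gn <- as.numeric(K %*% (H %*% dx - rs$f))
    step <- dx_gn - dx
    # step halving keeps the MAP objective non-increasing
    alpha <- 1
    for (h in 1:5) {
      dx_try <- dx + alpha * step
      rs_try <- resid_at(dx_try)
      if (!is.null(rs_try) && objective(dx_try, rs_try$f) <= obj + 1e-12) break
      alpha <- alpha / 2
    }
    dx_new <- dx + alpha * step
    rs_new <- resid_at(dx_new)
    if (is.null(rs_new)) break
    obj <- objective(dx_new, rs_new$f)
    obj_trace <- c(obj_trace, obj)
    moved <- sqrt(sum((dx_new - dx)^2))
    dx <- dx_new
    rs <- rs_new
    if (moved < tol) break
  }
  IKH <- diag(18) - K %*% H
  P_post <- IKH %*% P %*% t(IKH) + K %*% (meas_sigma^2 * diag(nrow(H))) %*% t(K)
  P_post <- (P_post + t(P_post)) / 2
  list(state = eskf_inject(state, dx), P = P_post, iterations = length(obj_trace),
       objective = obj_trace, n_matches = rs$n_edge + rs$n_plane, updated = TRUE)
}

#' Static initialization from a stationary IMU window
#'
#' Gravity is the mean accelerometer direction scaled to 9.81 m/s^2 (sign
#' flipped: at rest the specific force is -g in the body frame), the gyro
#' bias is the mean angular rate, and the residual mean specific force after
#' removing gravity becomes the accelerometer bias. The window must be
#' stationary: excess accelerometer variance raises an error.
#'
#' @param imu_window IMU samples (data.frame).
#' @param accel_var_threshold maximum allowed accelerometer variance,
#'   (m/s^2)^2.
#' @export
eskf_static_init <- function(imu_window, accel_var_threshold = 0.05) {
  A <- as.matrix(imu_window[, c("ax", "ay", "az")])
  W <- as.matrix(imu_window[, c("wx", "wy", "wz")])
  if (nrow(A) > 1 && max(apply(A, 2, stats::var)) > accel_var_threshold)
    stop("initialization error: motion detected during the static window")
  am <- colMeans(A)
  g <- -am / sqrt(sum(am^2)) * 9.81
  bg <- colMeans(W)
  ba <- am + g
  eskf_state(g = g, bg = bg, ba = ba)
}

#' LiDAR-inertial odometry over a sweep sequence
#'
#' Fuses IMU propagation with scan-to-scan feature matching in an iterated
#' error-state Kalman filter. The state is robocentric: at each sweep the
#' filter estimates the relative transform to the next sweep, seeded by IMU
#' integration, corrected by matching the next sweep's edge/planar features
#' against the current sweep's, then composed into the world-frame
#' trajectory. Gravity and gyro bias come from a static initialization
#' window at the start.
#'
#' @param scans list of scans (see [simulate_sweep_sequence()]); sweep start
#'   times in `attr(scans, "times")` or `sweep_times`.
#' @param imu IMU samples covering the sequence.
#' @param lidar the [lidar_model()].
#' @param sweep_times sweep start times (seconds), if not in the attribute.
#' @param init_window static initialization duration, seconds.
#' @param config list of preprocessing/update tuning values (see
#'   [default_config()]'s `preprocess` and `odometry` blocks).
#' @return list with `trajectory` (one pose per sweep) and `diagnostics`
#'   (per-frame iteration counts, match counts, residual norms).
#' @export
run_odometry <- function(scans, imu, lidar = lidar_model(), sweep_times = NULL,
                         init_window = 1, config = list()) {
  times <- sweep_times %||% attr(scans, "times")
  if (is.null(times)) stop("sweep times are required")
  stopifnot(length(times) == length(scans))
  period <- 1 / lidar$sweep_rate
  win <- imu[imu$timestamp <= times[1] + 1e-9 &
             imu$timestamp >= times[1] - init_window - 1e-9, ]
  if (nrow(win) < 10) stop("initialization error: static window has too few IMU samples")
  st0 <- eskf_static_init(win)
  noise <- list(gyro = config$gyro_noise %||% 0.003,
                accel = config$accel_noise %||% 0.012,
                gyro_rw = config$gyro_rw %||% 1e-5,
                accel_rw = config$accel_rw %||% 1e-4)
  meas_sigma <- config$meas_sigma %||% 0.1
  corr_radius <- config$corr_radius %||% 0.5
  # world pose of the current sweep frame
  T_w <- pose()
  v_b <- c(0, 0, 0)
  g_b <- st0$g
  ba <- st0$ba; bg <- st0$bg
  P <- eskf_initial_covariance(ba_sd = config$init_ba_sd %||% 1e-2,
                               bg_sd = config$init_bg_sd %||% 1e-3,
                               g_sd = config$init_g_sd %||% 1e-2)
  fs_prev <- preprocess_scan(scans[[1]], lidar, config)
  ref <- list(edge = feature_points(fs_prev, "edge"),
              planar = feature_points(fs_prev, "planar"))
  K <- length(scans)
  out <- matrix(0, K, 8)
  out[1, ] <- c(times[1], T_w$t, T_w$q[2:4], T_w$q[1])
  diag_rows <- vector("list", K - 1)
  for (k in 2:K) {
    seg <- imu[imu$timestamp >= times[k - 1] - 1e-9 & imu$timestamp <= times[k] + 1e-9, ]
    st <- eskf_state(p = c(0, 0, 0), v = v_b, q = quat_identity(),
                     ba = ba, bg = bg, g = g_b)
    pr <- eskf_propagate(st, P, seg, noise)
    # deskew the incoming sweep with the predicted interval motion
    # (sweeps are contiguous, so the interval motion approximates the
    # intra-sweep motion under near-constant velocity)
    T_pred <- pose(pr$state$p, pr$state$q)
    scan_k <- deskew_scan(scans[[k]], T_pred, sweep_period = period)
    fs_cur <- preprocess_scan(scan_k, lidar, config)
    up <- eskf_iterated_update(pr$state, pr$P, fs_cur, ref,
                               meas_sigma = meas_sigma,
                               max_iter = config$max_iter %||% 10,
                               tol = config$tol %||% 1e-6,
                               corr_radius = corr_radius)
    stp <- up$state
    T_rel <- pose(stp$p, stp$q)
    T_w <- pose_compose(T_w, T_rel)
    Rrel_t <- t(quat_to_rotmat(stp$q))
    v_b <- as.numeric(Rrel_t %*% stp$v)
    g_b <- as.numeric(Rrel_t %*% stp$g)
    ba <- stp$ba; bg <- stp$bg
    # re-anchor for the next relative interval: the new relative pose is
    # identically zero (tiny fresh covariance); the physical states --
    # velocity, biases, gravity -- carry their posterior marginals over,
    # with frame-carried blocks rotated into the new body frame
    P_next <- eskf_initial_covariance()
    carried <- c(ESKF_IV, ESKF_IBA, ESKF_IBG, ESKF_IG)
    Tc <- diag(12)
    Tc[1:3, 1:3] <- Rrel_t        # velocity rotates into the new frame
    Tc[10:12, 10:12] <- Rrel_t    # so does gravity
    P_next[carried, carried] <- Tc %*% up$P[carried, carried] %*% t(Tc)
    P <- P_next
    ref <- list(edge = feature_points(fs_cur, "edge"),
                planar = feature_points(fs_cur, "planar"))
    out[k, ] <- c(times[k], T_w$t, T_w$q[2:4], T_w$q[1])
    diag_rows[[k - 1]] <- data.frame(frame = k, iterations = up$iterations,
                                     n_matches = up$n_matches,
                                     updated = up$updated,
                                     final_objective = if (length(up$objective)) utils::tail(up$objective, 1) else NA_real_)
  }
  traj <- data.frame(timestamp = out[, 1], tx = out[, 2], ty = out[, 3], tz = out[, 4],
                     qx = out[, 5], qy = out[, 6], qz = out[, 7], qw = out[, 8])
  class(traj) <- c("trajectory", "data.frame")
  list(trajectory = traj, diagnostics = do.call(rbind, diag_rows))
}
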