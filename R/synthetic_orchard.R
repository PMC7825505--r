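#' Sensor models
#'
#' `lidar_model()` describes a 16-beam spinning LiDAR (vertical field of view
#' +/- 15 degrees, 1800 azimuth steps per sweep at 10 Hz, +/- 2 cm range
#' noise, 150 m maximum range). `imu_model()` describes a strapdown IMU
#' sampled at 400 Hz with per-sample white-noise standard deviations and
#' constant biases; gravity defaults to 9.81 m/s^2 pointing down.
#'
#' @param n_beams number of LiDAR rings.
#' @param vertical_fov half field of view, degrees; rings are spaced evenly
#'   over `[-vertical_fov, +vertical_fov]`.
#' @param azimuth_steps azimuth bins per 360 degree sweep.
#' @param range_sigma 1-sigma range noise, metres.
#' @param max_range maximum usable range, metres.
#' @param sweep_rate sweeps per second, Hz.
#' @export
lidar_model <- function(n_beams = 16, vertical_fov = 15, azimuth_steps = 1800,
                        range_sigma = 0.02, max_range = 150, sweep_rate = 10) {
  stopifnot(n_beams >= 2, azimuth_steps >= 4, range_sigma >= 0,
            max_range > 0, sweep_rate > 0)
  structure(list(
    n_beams = n_beams,
    vertical_fov = vertical_fov,
    azimuth_steps = azimuth_steps,
    range_sigma = range_sigma,
    max_range = max_range,
    sweep_rate = sweep_rate,
    elevations = seq(-vertical_fov, vertical_fov, length.out = n_beams),
    azimuth_res = 360 / azimuth_steps
  ), class = "lidar_model")
}

#' @rdname lidar_model
#' @param rate IMU sample rate, Hz (must exceed the LiDAR sweep rate).
#' @param gyro_bias,accel_bias constant biases (rad/s, m/s^2), length 3.
#' @param gyro_noise,accel_noise per-sample white-noise standard deviations
#'   (rad/s, m/s^2).
#' @param gravity gravity vector in the world frame, m/s^2.
#' @export
imu_model <- function(rate = 400, gyro_bias = c(0, 0, 0), accel_bias = c(0, 0, 0),
                      gyro_noise = 0.003, accel_noise = 0.012,
                      gravity = c(0, 0, -9.81)) {
  gn <- sqrt(sum(gravity^2))
  if (gn < 9.7 || gn > 9.9) stop("|gravity| must lie in [9.7, 9.9] m/s^2")
  stopifnot(rate > 10, gyro_noise >= 0, accel_noise >= 0,
            length(gyro_bias) == 3, length(accel_bias) == 3)
  structure(list(rate = rate, gyro_bias = gyro_bias, accel_bias = accel_bias,
                 gyro_noise = gyro_noise, accel_noise = accel_noise,
                 gravity = gravity), class = "imu_model")
}

#' Generate a ground-truthed synthetic orchard scene
#'
#' Trees sit on a row lattice (5 m between rows, 4 m within a row by
#' default, matching a standardized commercial orchard) with small position
#' jitter. Crowns are solid ellipsoids or cones parameterised by diameter
#' `x` and height `y`, raised `base_height` above a flat ground plane; a few
#' trees are markedly smaller, emulating dead or stunted individuals. A
#' requested fraction of in-row adjacent pairs gets large same-height
#' crowns pulled close together (within the jitter budget); their canopies
#' are joined by sparse branch bridges during sampling, so the two-step
#' segmentation has connected canopies to split.
#'
#' The world frame is anchored at the sensor start position: z = 0 at the
#' sensor, ground plane at z = -sensor_height.
#'
#' @param n_rows,trees_per_row lattice dimensions.
#' @param overlap_fraction fraction of in-row adjacent pairs whose crown
#'   surfaces come within the clustering radius, in `[0, 1]`.
#' @param seed RNG seed (required for reproducibility).
#' @param row_spacing,in_row_spacing lattice spacing, metres.
#' @param sensor_height LiDAR mount height above ground, metres.
#' @return an `orchard_scene`: ground plane coefficients, a tree table
#'   (`id, cx, cy, shape, x, y, base_height`), overlap-pair table, spacings
#'   and scene bounds.
#' @export
generate_scene <- function(n_rows, trees_per_row, overlap_fraction = 0, seed,
                           row_spacing = 5, in_row_spacing = 4,
                           sensor_height = 0.8) {
  if (n_rows < 1 || trees_per_row < 1) stop("tree counts must be positive")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]")
  if (missing(seed)) stop("seed is required")
  with_seed(seed, {
    n <- n_rows * trees_per_row
    grid <- expand.grid(col = seq_len(trees_per_row), row = seq_len(n_rows))
    trees <- data.frame(
      id = seq_len(n),
      row = grid$row,
      col = grid$col,
      cx = (grid$col - 1) * in_row_spacing + stats::runif(n, -0.15, 0.15),
      cy = (grid$row - 1) * row_spacing + stats::runif(n, -0.15, 0.15),
      shape = sample(c("ellipsoid", "cone"), n, replace = TRUE, prob = c(0.7, 0.3)),
      x = stats::runif(n, 1.5, 3.0),
      y = stats::runif(n, 1.5, 3.0),
      base_height = stats::runif(n, 0.3, 0.8),
      stringsAsFactors = FALSE
    )
    # a few dead / stunted trees
    small <- stats::runif(n) < 0.05
    trees$x[small] <- pmax(0.8, trees$x[small] * 0.5)
    trees$y[small] <- pmax(0.8, trees$y[small] * 0.5)
    # overlapping crown pairs: in-row neighbours, disjoint, chosen at random
    pairs <- data.frame(a = integer(), b = integer())
    if (overlap_fraction > 0 && trees_per_row >= 2) {
      cand <- which(grid$col < trees_per_row)  # pair (i, i+1) within a row
      n_pairs <- round(overlap_fraction * length(cand))
      used <- rep(FALSE, n)
      chosen <- integer()
      for (i in sample(cand)) {
        if (length(chosen) >= n_pairs) break
        if (used[i] || used[i + 1]) next
        chosen <- c(chosen, i)
        used[c(i, i + 1)] <- TRUE
      }
      chosen <- sort(chosen)
      pairs <- data.frame(a = chosen, b = chosen + 1L)
      for (k in seq_len(nrow(pairs))) {
        a <- pairs$a[k]; b <- pairs$b[k]
        # large same-height ellipsoid crowns pulled close; their canopies
        # are joined by sparse branch bridges (see sample_scene_points),
        # the crown envelopes themselves keep a small standoff
        trees$shape[c(a, b)] <- "ellipsoid"
        trees$x[c(a, b)] <- stats::runif(2, 3.2, 3.5)
        trees$y[a] <- trees$y[b] <- stats::runif(1, 2.2, 3.0)
        trees$base_height[a] <- trees$base_height[b] <- stats::runif(1, 0.3, 0.8)
        gap_target <- (trees$x[a] + trees$x[b]) / 2 + stats::runif(1, 0.30, 0.45)
        pull <- (in_row_spacing - gap_target) / 2
        trees$cx[a] <- (grid$col[a] - 1) * in_row_spacing + pull
        trees$cx[b] <- (grid$col[b] - 1) * in_row_spacing - pull
        trees$cy[b] <- trees$cy[a]
      }
    }
    margin <- 6
    bounds <- list(
      xlim = c(-margin, (trees_per_row - 1) * in_row_spacing + margin),
      ylim = c(-margin, (n_rows - 1) * row_spacing + margin)
    )
    structure(list(
      ground = c(0, 0, 1, sensor_height),  # z = -sensor_height
      trees = trees,
      overlap_pairs = pairs,
      row_spacing = row_spacing,
      in_row_spacing = in_row_spacing,
      sensor_height = sensor_height,
      bounds = bounds,
      seed = seed
    ), class = "orchard_scene")
  })
}

#' @export
print.orchard_scene <- function(x, ...) {
  cat("orchard scene:", nrow(x$trees), "trees,",
      x$row_spacing, "m row spacing,", x$in_row_spacing, "m in-row spacing,",
      nrow(x$overlap_pairs), "overlapping pair(s)\n")
  invisible(x)
}

crown_area <- function(shape, x, y) {
  a <- x / 2; c <- y / 2
  if (shape == "ellipsoid") {
    # Thomsen approximation of the ellipsoid surface area
    p <- 1.6075
    4 * pi * (((a * a)^p + 2 * (a * c)^p) / 3)^(1 / p)
  } else {
    # cone lateral surface
    pi * a * sqrt(a^2 + y^2)
  }
}

sample_ellipsoid_surface <- function(n, a, c) {
  if (n <= 0) return(matrix(numeric(0), ncol = 3))
  out <- matrix(numeric(0), ncol = 3)
  while (nrow(out) < n) {
    m <- max(64, ceiling((n - nrow(out)) * 1.6))
    u <- matrix(stats::rnorm(3 * m), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    # area-element weight for x = diag(a, a, c) u
    w <- sqrt((a * c * u[, 1])^2 + (a * c * u[, 2])^2 + (a * a * u[, 3])^2)
    keep <- stats::runif(m) < w / max(a * c, a * a)
    pts <- cbind(a * u[keep, 1], a * u[keep, 2], c * u[keep, 3])
    out <- rbind(out, pts)
  }
  out[seq_len(n), , drop = FALSE]
}

sample_tree_points <- function(tree, n_surface, n_interior) {
  a <- tree$x / 2
  if (tree$shape == "ellipsoid") {
    c_ <- tree$y / 2
    zc <- tree$base_height + c_
    surf <- sample_ellipsoid_surface(n_surface, a, c_)
    surf[, 3] <- surf[, 3] + zc
    u <- matrix(stats::rnorm(3 * n_interior), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * stats::runif(n_interior)^(1 / 3)
    intr <- cbind(a * u[, 1], a * u[, 2], c_ * u[, 3] + zc)
  } else {
    h <- tree$y
    za <- tree$base_height + h
    k <- a / h
    # lateral surface: area density proportional to distance below apex
    d <- h * sqrt(stats::runif(n_surface))
    th <- stats::runif(n_surface, 0, 2 * pi)
    surf <- cbind(k * d * cos(th), k * d * sin(th), za - d)
    d2 <- h * stats::runif(n_interior)^(1 / 3)
    r2 <- k * d2 * sqrt(stats::runif(n_interior))
    th2 <- stats::runif(n_interior, 0, 2 * pi)
    intr <- cbind(r2 * cos(th2), r2 * sin(th2), za - d2)
  }
  pts <- rbind(surf, intr)
  pts[, 1] <- pts[, 1] + tree$cx
  pts[, 2] <- pts[, 2] + tree$cy
  pts
}

#' Sample a labeled point cloud from a scene
#'
#' Emulates the point density of an assembled mobile-LiDAR map: crown points
#' are drawn on the crown surface (the canopy envelope the sensor sees) with
#' a fraction in the crown interior (returns from inner foliage), ground
#' points uniformly on the ground plane, and -- for overlapping pairs -- a
#' sparse scattered "bridge" of points between the two crowns emulating
#' interpenetrating branches. Every point is perturbed by isotropic Gaussian
#' noise and carries its ground-truth label (0 = ground, tree id otherwise).
#'
#' @param scene an `orchard_scene`.
#' @param density crown points per m^2 of crown surface.
#' @param sigma isotropic noise standard deviation, metres.
#' @param seed RNG seed.
#' @param ground_density ground points per m^2 (0 to omit the ground).
#' @param interior_fraction fraction of crown points drawn inside the solid.
#' @param bridge_points scattered points per overlapping pair.
#' @return `data.frame(x, y, z, label)`.
#' @export
sample_scene_points <- function(scene, density = 1500, sigma = 0.02, seed,
                                ground_density = 250, interior_fraction = 0.35,
                                bridge_points = 400) {
  stopifnot(inherits(scene, "orchard_scene"), density > 0)
  if (missing(seed)) stop("seed is required")
  with_seed(seed, {
    parts <- list()
    if (ground_density > 0) {
      area <- diff(scene$bounds$xlim) * diff(scene$bounds$ylim)
      ng <- round(ground_density * area)
      parts$ground <- cbind(stats::runif(ng, scene$bounds$xlim[1], scene$bounds$xlim[2]),
                            stats::runif(ng, scene$bounds$ylim[1], scene$bounds$ylim[2]),
                            -scene$sensor_height, 0)
    }
    for (i in seq_len(nrow(scene$trees))) {
      tr <- scene$trees[i, ]
      n_tot <- round(density * crown_area(tr$shape, tr$x, tr$y))
      n_int <- round(n_tot * interior_fraction)
      pts <- sample_tree_points(tr, n_tot - n_int, n_int)
      pts[, 3] <- pts[, 3] - scene$sensor_height
      parts[[length(parts) + 1]] <- cbind(pts, tr$id)
    }
    if (nrow(scene$overlap_pairs) > 0 && bridge_points > 0) {
      # interpenetrating branch tips joining the two canopies: a few thin,
      # densely sampled line segments spanning the inter-crown gap -- dense
      # enough to connect the pair at the clustering radius, but with
      # line-like neighbourhoods whose mean-kNN distances are far outside
      # the crown bulk (so SOR strips them)
      for (k in seq_len(nrow(scene$overlap_pairs))) {
        ta <- scene$trees[scene$overlap_pairs$a[k], ]
        tb <- scene$trees[scene$overlap_pairs$b[k], ]
        n_branch <- 6
        dirx <- sign(tb$cx - ta$cx)
        zca <- ta$base_height + ta$y / 2 - scene$sensor_height
        zcb <- tb$base_height + tb$y / 2 - scene$sensor_height
        bp <- NULL
        for (bidx in seq_len(n_branch)) {
          # a branch tip crossing the gap between the two facing caps
          y0 <- ta$cy + stats::runif(1, -0.35, 0.35)
          z0 <- zca + stats::runif(1, -0.5, 0.5) * ta$y / 2 * 0.7
          sa <- sqrt(max(0.2, 1 - ((y0 - ta$cy) / (ta$x / 2))^2 -
                                ((z0 - zca) / (ta$y / 2))^2))
          sb <- sqrt(max(0.2, 1 - ((y0 - tb$cy) / (tb$x / 2))^2 -
                                ((z0 - zcb) / (tb$y / 2))^2))
          pa <- c(ta$cx + dirx * (ta$x / 2) * sa - dirx * 0.10, y0, z0)
          pb <- c(tb$cx - dirx * (tb$x / 2) * sb + dirx * 0.10, y0, z0)
          per <- max(2, ceiling(bridge_points / n_branch),
                     ceiling(sqrt(sum((pb - pa)^2)) / 0.005))
          tt <- seq(0, 1, length.out = per)
          seg <- cbind(pa[1] + tt * (pb[1] - pa[1]),
                       pa[2] + tt * (pb[2] - pa[2]),
                       pa[3] + tt * (pb[3] - pa[3])) +
            matrix(stats::rnorm(3 * per, 0, 0.003), ncol = 3)
          bp <- rbind(bp, seg)
        }
        lab <- ifelse((bp[, 1] - ta$cx)^2 + (bp[, 2] - ta$cy)^2 <
                        (bp[, 1] - tb$cx)^2 + (bp[, 2] - tb$cy)^2, ta$id, tb$id)
        parts[[length(parts) + 1]] <- cbind(bp, lab)
      }
    }
    m <- do.call(rbind, parts)
    if (sigma > 0) m[, 1:3] <- m[, 1:3] + stats::rnorm(3 * nrow(m), 0, sigma)
    data.frame(x = m[, 1], y = m[, 2], z = m[, 3], label = as.integer(m[, 4]))
  })
}

# ---- trajectory + IMU simulation --------------------------------------------

# A trajectory segment supplies analytic position/velocity/acceleration and
# z-y-x Euler angles with rates at local time tau in [0, duration].
#
# The default route is C^1 in both velocity and angular velocity: smoothstep
# speed ramps, straights, and spin-in-place turns with smoothstep yaw (a
# tracked robot turns on the spot). Discontinuous rates cannot be
# represented by sampled IMU data, so any kink would leak a permanent
# attitude/velocity error into downstream integration. The classical
# constant-rate arc turn is kept as an option (turn_style = "arc").
RAMP_T <- 2    # s, smoothstep speed ramps
SPIN_T <- 2.5  # s, smoothstep in-place turns

seg_ramp <- function(p0, dir, v, up = TRUE) {
  list(kind = "ramp", duration = RAMP_T, p0 = p0, dir = dir, v = v, up = up)
}

make_segments <- function(scene, speed, corridors, static_time,
                          pitch_amp, roll_amp, perturb_freq,
                          turn_style = "spin") {
  xr <- scene$bounds$xlim + c(2, -2)
  segs <- list()
  if (static_time > 0)
    segs[[1]] <- list(kind = "static", duration = static_time,
                      p0 = c(xr[1], corridors[1], 0), yaw = 0)
  dir_sign <- 1
  ramp_d <- speed * RAMP_T / 2
  for (ci in seq_along(corridors)) {
    y <- corridors[ci]
    x0 <- if (dir_sign > 0) xr[1] else xr[2]
    dirv <- c(dir_sign, 0, 0)
    yaw <- if (dir_sign > 0) 0 else pi
    L <- diff(xr)
    if (turn_style == "spin" || ci == 1) {
      segs[[length(segs) + 1]] <- seg_ramp(c(x0, y, 0), dirv, speed, up = TRUE)
      x0 <- x0 + dir_sign * ramp_d
      L <- L - ramp_d
    }
    if (turn_style == "spin" && ci < length(corridors)) L <- L - ramp_d
    segs[[length(segs) + 1]] <- list(kind = "straight", duration = L / speed,
                                     p0 = c(x0, y, 0), dir = dirv, speed = speed)
    x_end <- x0 + dir_sign * L
    if (ci < length(corridors)) {
      gap <- corridors[ci + 1] - y
      if (turn_style == "spin") {
        # stop, turn on the spot, cross to the next corridor, turn again
        segs[[length(segs) + 1]] <- seg_ramp(c(x_end, y, 0), dirv, speed, up = FALSE)
        stop_p <- c(x_end + dir_sign * ramp_d, y, 0)
        segs[[length(segs) + 1]] <- list(kind = "spin", duration = SPIN_T,
                                         p0 = stop_p, yaw0 = yaw,
                                         dyaw = pi / 2 - yaw)
        vc <- min(speed, 1)
        rc <- vc * RAMP_T / 2
        segs[[length(segs) + 1]] <- seg_ramp(stop_p, c(0, 1, 0), vc, up = TRUE)
        segs[[length(segs) + 1]] <- list(kind = "straight",
                                         duration = (gap - 2 * rc) / vc,
                                         p0 = stop_p + c(0, rc, 0),
                                         dir = c(0, 1, 0), speed = vc)
        segs[[length(segs) + 1]] <- seg_ramp(stop_p + c(0, gap - rc, 0),
                                             c(0, 1, 0), vc, up = FALSE)
        yaw_next <- if (dir_sign > 0) pi else 0
        segs[[length(segs) + 1]] <- list(kind = "spin", duration = SPIN_T,
                                         p0 = stop_p + c(0, gap, 0),
                                         yaw0 = pi / 2, dyaw = yaw_next - pi / 2)
      } else {
        r <- gap / 2
        segs[[length(segs) + 1]] <- list(kind = "arc", duration = pi * abs(r) / speed,
                                         centre = c(x_end, y + r, 0), radius = r,
                                         start_angle = if (dir_sign > 0) -pi / 2 else pi / 2,
                                         ccw = dir_sign > 0, speed = speed)
      }
    }
    dir_sign <- -dir_sign
  }
  attr(segs, "perturb") <- list(pitch_amp = pitch_amp, roll_amp = roll_amp,
                                freq = perturb_freq, t0 = static_time)
  segs
}

# smoothstep and its derivative
sstep <- function(u) u^2 * (3 - 2 * u)
sstep_d <- function(u) 6 * u * (1 - u)

eval_segment <- function(seg, tau) {
  if (seg$kind == "static") {
    list(p = seg$p0, v = c(0, 0, 0), a = c(0, 0, 0),
         yaw = seg$yaw, yaw_rate = 0)
  } else if (seg$kind == "ramp") {
    # smoothstep speed profile: acceleration is continuous (0 at both ends)
    u <- tau / seg$duration
    T <- seg$duration
    yaw <- atan2(seg$dir[2], seg$dir[1])
    dist_up <- seg$v * T * (u^3 - u^4 / 2)
    if (seg$up) {
      list(p = seg$p0 + dist_up * seg$dir,
           v = seg$v * sstep(u) * seg$dir,
           a = seg$v * sstep_d(u) / T * seg$dir,
           yaw = yaw, yaw_rate = 0)
    } else {
      list(p = seg$p0 + (seg$v * tau - dist_up) * seg$dir,
           v = seg$v * (1 - sstep(u)) * seg$dir,
           a = -seg$v * sstep_d(u) / T * seg$dir,
           yaw = yaw, yaw_rate = 0)
    }
  } else if (seg$kind == "straight") {
    list(p = seg$p0 + seg$speed * tau * seg$dir,
         v = seg$speed * seg$dir, a = c(0, 0, 0),
         yaw = atan2(seg$dir[2], seg$dir[1]), yaw_rate = 0)
  } else if (seg$kind == "spin") {
    u <- tau / seg$duration
    list(p = seg$p0, v = c(0, 0, 0), a = c(0, 0, 0),
         yaw = seg$yaw0 + seg$dyaw * sstep(u),
         yaw_rate = seg$dyaw * sstep_d(u) / seg$duration)
  } else {
    w <- seg$speed / abs(seg$radius) * (if (seg$ccw) 1 else -1)
    ang <- seg$start_angle + w * tau
    r <- abs(seg$radius)
    p <- seg$centre + c(r * cos(ang), r * sin(ang), 0)
    v <- seg$speed * c(-sin(ang), cos(ang), 0) * (if (seg$ccw) 1 else -1)
    a <- -r * w^2 * c(cos(ang), sin(ang), 0)
    yaw <- ang + (if (seg$ccw) pi / 2 else -pi / 2)
    list(p = p, v = v, a = a, yaw = yaw, yaw_rate = w)
  }
}

# exact body angular velocity for R = Rz(yaw) Ry(pitch) Rx(roll)
euler_zyx_to_quat <- function(yaw, pitch, roll) {
  quat_multiply(quat_exp_map(c(0, 0, yaw)),
                quat_multiply(quat_exp_map(c(0, pitch, 0)),
                              quat_exp_map(c(roll, 0, 0))))
}

euler_body_rates <- function(yaw_rate, pitch, pitch_rate, roll, roll_rate) {
  c(roll_rate, 0, 0) +
    as.numeric(t(quat_to_rotmat(quat_exp_map(c(roll, 0, 0)))) %*% c(0, pitch_rate, 0)) +
    as.numeric(t(quat_to_rotmat(quat_exp_map(c(roll, 0, 0)))) %*%
               t(quat_to_rotmat(quat_exp_map(c(0, pitch, 0)))) %*% c(0, 0, yaw_rate))
}

#' Simulate the robot trajectory and its IMU stream
#'
#' Drives a serpentine route through the orchard's inter-row corridors,
#' starting from a stationary dwell (used by the odometry's static
#' initialization): smoothstep speed ramps, constant-speed straights, and
#' spin-in-place turns between corridors (a tracked platform turns on the
#' spot); `turn_style = "arc"` substitutes classical constant-rate
#' half-circle turns. The default route is C^1 in velocity and angular
#' velocity -- rate discontinuities cannot be represented by sampled IMU
#' data and would leak permanent attitude errors into any integrator.
#' Small enveloped sinusoidal pitch/roll perturbations emulate the platform
#' rocking over rough ground. IMU angular velocity and specific force are
#' computed analytically from the trajectory, then bias and white noise
#' from the `imu_model` are added.
#'
#' @param turn_style `"spin"` (default) or `"arc"`.
#'
#' @param scene an `orchard_scene`.
#' @param speed platform speed, m/s.
#' @param seed RNG seed for IMU noise.
#' @param imu an [imu_model()].
#' @param static_time stationary dwell before motion, seconds.
#' @param corridors corridor y-positions to traverse (default: all inter-row
#'   corridors, or one corridor beside a single row).
#' @param pitch_amp,roll_amp perturbation amplitudes, degrees.
#' @param perturb_freq perturbation frequency, Hz.
#' @return list with `trajectory` (pose stream at IMU rate) and `imu`
#'   (samples at the same timestamps).
#' @export
simulate_trajectory <- function(scene, speed = 1, seed = NULL, imu = imu_model(),
                                static_time = 1, corridors = NULL,
                                pitch_amp = 0.5, roll_amp = 0.3,
                                perturb_freq = 0.4,
                                turn_style = c("spin", "arc")) {
  turn_style <- match.arg(turn_style)
  stopifnot(speed > 0)
  if (is.null(corridors)) {
    n_rows <- max(scene$trees$row)
    corridors <- if (n_rows > 1) (seq_len(n_rows - 1) - 0.5) * scene$row_spacing
                 else -scene$row_spacing / 2
  }
  segs <- make_segments(scene, speed, corridors, static_time,
                        pitch_amp * pi / 180, roll_amp * pi / 180,
                        perturb_freq, turn_style = turn_style)
  pert <- attr(segs, "perturb")
  total <- sum(vapply(segs, `[[`, numeric(1), "duration"))
  dt <- 1 / imu$rate
  times <- seq(0, total, by = dt)
  n <- length(times)
  starts <- cumsum(c(0, vapply(segs, `[[`, numeric(1), "duration")))
  g <- imu$gravity
  traj <- matrix(0, n, 8)
  imu_m <- matrix(0, n, 7)
  seg_idx <- 1
  for (i in seq_len(n)) {
    t <- times[i]
    while (seg_idx < length(segs) && t > starts[seg_idx + 1] + 1e-12) seg_idx <- seg_idx + 1
    st <- eval_segment(segs[[seg_idx]], t - starts[seg_idx])
    moving <- segs[[seg_idx]]$kind != "static"
    if (moving && (pert$pitch_amp > 0 || pert$roll_amp > 0)) {
      # smoothstep envelope over the first 2 s of motion so the rocking
      # starts with zero angle AND zero rate
      te <- t - pert$t0
      u <- min(1, te / 2)
      e <- sstep(u)
      e_dot <- if (u < 1) sstep_d(u) / 2 else 0
      w_ph <- 2 * pi * pert$freq
      ph <- w_ph * te
      pitch <- pert$pitch_amp * sin(ph) * e
      pitch_rate <- pert$pitch_amp * (cos(ph) * w_ph * e + sin(ph) * e_dot)
      roll <- pert$roll_amp * sin(ph * 0.7) * e
      roll_rate <- pert$roll_amp * (cos(ph * 0.7) * 0.7 * w_ph * e + sin(ph * 0.7) * e_dot)
    } else {
      pitch <- pitch_rate <- roll <- roll_rate <- 0
    }
    q <- euler_zyx_to_quat(st$yaw, pitch, roll)
    w_body <- euler_body_rates(st$yaw_rate, pitch, pitch_rate, roll, roll_rate)
    R <- quat_to_rotmat(q)
    f_body <- as.numeric(t(R) %*% (st$a - g))
    traj[i, ] <- c(t, st$p, q[2], q[3], q[4], q[1])
    imu_m[i, ] <- c(t, w_body, f_body)
  }
  imu_df <- data.frame(timestamp = imu_m[, 1],
                       wx = imu_m[, 2] + imu$gyro_bias[1],
                       wy = imu_m[, 3] + imu$gyro_bias[2],
                       wz = imu_m[, 4] + imu$gyro_bias[3],
                       ax = imu_m[, 5] + imu$accel_bias[1],
                       ay = imu_m[, 6] + imu$accel_bias[2],
                       az = imu_m[, 7] + imu$accel_bias[3])
  if (!is.null(seed) && (imu$gyro_noise > 0 || imu$accel_noise > 0)) {
    imu_df <- with_seed(seed, {
      imu_df[, 2:4] <- imu_df[, 2:4] + stats::rnorm(3 * n, 0, imu$gyro_noise)
      imu_df[, 5:7] <- imu_df[, 5:7] + stats::rnorm(3 * n, 0, imu$accel_noise)
      imu_df
    })
  }
  traj_df <- data.frame(timestamp = traj[, 1], tx = traj[, 2], ty = traj[, 3],
                        tz = traj[, 4], qx = traj[, 5], qy = traj[, 6],
                        qz = traj[, 7], qw = traj[, 8])
  class(traj_df) <- c("trajectory", "data.frame")
  list(trajectory = traj_df, imu = imu_df)
}

#' Interpolate a pose from a trajectory
#'
#' Linear interpolation for translation, spherical for rotation.
#'
#' @param traj trajectory `data.frame`.
#' @param t query time, seconds.
#' @export
traj_pose_at <- function(traj, t) {
  ts <- traj$timestamp
  if (t <= ts[1]) i <- 1 else i <- findInterval(t, ts)
  if (i >= length(ts)) {
    r <- traj[length(ts), ]
    return(pose(c(r$tx, r$ty, r$tz), c(r$qw, r$qx, r$qy, r$qz)))
  }
  u <- (t - ts[i]) / (ts[i + 1] - ts[i])
  a <- traj[i, ]; b <- traj[i + 1, ]
  pose(t = (1 - u) * c(a$tx, a$ty, a$tz) + u * c(b$tx, b$ty, b$tz),
       q = quat_slerp(c(a$qw, a$qx, a$qy, a$qz), c(b$qw, b$qx, b$qy, b$qz), u))
}

#' Simulate one LiDAR sweep
#'
#' Casts one ray per (beam, azimuth step) from the sensor pose, returning the
#' first analytic intersection with the ground plane or a crown surface
#' (quadric/cone), perturbed by Gaussian range noise. When `pose_end` is
#' given, the sensor pose is interpolated across the sweep so the scan
#' carries genuine motion distortion; points are always expressed in the
#' sensor frame as a real device would report them (range and beam angles,
#' ignorant of its own motion). Misses are simply absent.
#'
#' @param scene an `orchard_scene`.
#' @param pose_ sensor pose at sweep start ([pose()]).
#' @param lidar a [lidar_model()].
#' @param seed RNG seed for range noise.
#' @param pose_end sensor pose at sweep end (optional; default static sweep).
#' @return scan `data.frame(x, y, z, ring, time_offset, label, range)` with
#'   the start pose attached as attribute `"pose"`.
#' @export
simulate_scan <- function(scene, pose_, lidar = lidar_model(), seed = NULL,
                          pose_end = NULL) {
  stopifnot(inherits(scene, "orchard_scene"), inherits(pose_, "se3_pose"))
  n_az <- lidar$azimuth_steps
  u <- (seq_len(n_az) - 1) / n_az
  if (is.null(pose_end)) {
    origins <- matrix(pose_$t, n_az, 3, byrow = TRUE)
    quats <- matrix(pose_$q, n_az, 4, byrow = TRUE)
  } else {
    origins <- cbind((1 - u) * pose_$t[1] + u * pose_end$t[1],
                     (1 - u) * pose_$t[2] + u * pose_end$t[2],
                     (1 - u) * pose_$t[3] + u * pose_end$t[3])
    quats <- t(vapply(u, function(ui) quat_slerp(pose_$q, pose_end$q, ui), numeric(4)))
  }
  trees <- scene$trees
  tm <- cbind(ifelse(trees$shape == "cone", 1, 0), trees$cx, trees$cy,
              trees$base_height - scene$sensor_height, trees$x, trees$y)
  res <- with_seed(seed,
    cpp_raycast(origins, quats, lidar$elevations, scene$ground, TRUE,
                tm, lidar$range_sigma, 0.2, lidar$max_range))
  scan <- data.frame(x = res$x, y = res$y, z = res$z,
                     ring = as.integer(res$ring),
                     time_offset = res$col / (n_az * lidar$sweep_rate),
                     label = as.integer(res$label),
                     range = res$range)
  attr(scan, "pose") <- pose_
  attr(scan, "lidar") <- lidar
  scan
}

#' Simulate a sequence of motion-distorted sweeps along a trajectory
#'
#' @param scene an `orchard_scene`.
#' @param traj trajectory `data.frame` (e.g. from [simulate_trajectory()]).
#' @param lidar a [lidar_model()].
#' @param times sweep start times; default: the full trajectory span at the
#'   sweep rate.
#' @param seed RNG seed; each sweep derives its own sub-seed.
#' @return list of scans (see [simulate_scan()]) with attribute `"times"`.
#' @export
simulate_sweep_sequence <- function(scene, traj, lidar = lidar_model(),
                                    times = NULL, seed = NULL) {
  period <- 1 / lidar$sweep_rate
  if (is.null(times))
    times <- seq(traj$timestamp[1], max(traj$timestamp) - period, by = period)
  scans <- vector("list", length(times))
  for (i in seq_along(times)) {
    p0 <- traj_pose_at(traj, times[i])
    p1 <- traj_pose_at(traj, times[i] + period)
    s <- if (is.null(seed)) NULL else seed + i
    scans[[i]] <- simulate_scan(scene, p0, lidar, seed = s, pose_end = p1)
  }
  attr(scans, "times") <- times
  scans
}
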