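# a small deterministic scan for grid-level tests: points placed exactly at
# the bin centres of chosen cells
cell_scan <- function(cells, ranges, lidar = lidar_model()) {
  az <- (cells$col - 0.5) * lidar$azimuth_res * pi / 180
  el <- lidar$elevations[cells$ring + 1] * pi / 180
  data.frame(x = ranges * cos(el) * cos(az),
             y = ranges * cos(el) * sin(az),
             z = ranges * sin(el),
             ring = cells$ring,
             time_offset = (cells$col - 1) / (lidar$azimuth_steps * lidar$sweep_rate))
}

test_that("deskewing applies the fractional sweep transform", {
  sc <- single_tree_scene()
  scan <- simulate_scan(sc, pose(), lidar_model(range_sigma = 0), seed = NULL)
  # identity transform leaves the scan unchanged
  out <- deskew_scan(scan, pose())
  expect_equal(out$x, scan$x, tolerance = 1e-12)

  # a point at the sweep end with a pure translation gets the full shift
  toy <- data.frame(x = c(1, 1), y = 0, z = 0, time_offset = c(0, 0.1))
  out <- deskew_scan(toy, pose(t = c(1, 0, 0)))
  expect_equal(out$x, c(1, 2), tolerance = 1e-12)

  # half-offset point under a 10 degree yaw gets a 5 degree yaw, matching
  # direct pose interpolation
  q10 <- quat_exp_map(c(0, 0, 10 * pi / 180))
  toy2 <- data.frame(x = 1, y = 2, z = 0.5, time_offset = 0.05)
  out2 <- deskew_scan(toy2, pose(q = q10))
  direct <- quat_rotate(quat_slerp(quat_identity(), q10, 0.5), c(1, 2, 0.5))
  expect_equal(c(out2$x, out2$y, out2$z), direct, tolerance = 1e-12)

  expect_error(deskew_scan(data.frame(x = 1, y = 1, z = 1), pose()), "time_offset")
})

test_that("range-image projection places points in the right cells", {
  scan <- data.frame(x = c(1, 0), y = c(0, 1), z = 0, ring = c(0L, 3L),
                     time_offset = 0)
  img <- project_range_image(scan)
  expect_equal(dim(img$range), c(16, 1800))
  expect_equal(img$range[1, 1], 1)
  expect_equal(img$range[4, 451], 1)  # 90 deg / 0.2 deg -> column 450 (0-based)

  # occupied cells always carry the back-referenced point's norm
  sc <- single_tree_scene()
  scan2 <- simulate_scan(sc, pose(), lidar_model(), seed = 13)
  img2 <- project_range_image(scan2)
  occ <- which(!is.na(img2$idx))
  norms <- sqrt(scan2$x^2 + scan2$y^2 + scan2$z^2)
  expect_equal(img2$range[occ], norms[img2$idx[occ]], tolerance = 1e-12)
})

test_that("ground labeling finds the plane and ignores walls", {
  # flat plane: nearly all returns labeled ground
  sc <- ground_only_scene()
  scan <- simulate_scan(sc, pose(), lidar_model(), seed = 14)
  img <- label_ground(project_range_image(scan), threshold = 10)
  labeled <- img$ground[!is.na(img$idx)]
  expect_gt(mean(labeled[rowSums(!is.na(img$idx)) > 0]), 0)
  expect_gt(sum(img$ground) / nrow(scan), 0.99)

  # a vertical wall yields no ground labels
  lid <- lidar_model()
  cells <- expand.grid(ring = 0:7, col = 1:50)
  el <- lid$elevations[cells$ring + 1] * pi / 180
  az <- (cells$col - 0.5) * lid$azimuth_res * pi / 180
  rng <- 5 / (cos(el) * cos(az))  # wall at x = 5
  wall <- cell_scan(cells, rng)
  img2 <- label_ground(project_range_image(wall), threshold = 10)
  expect_equal(sum(img2$ground), 0)

  # degenerate threshold 0: nothing is ground
  img3 <- label_ground(project_range_image(scan), threshold = 0)
  expect_equal(sum(img3$ground), 0)
})

test_that("BFS clustering matches connected components and drops specks", {
  # two crowns well apart -> two clusters matching the truth labels
  sc <- generate_scene(1, 2, overlap_fraction = 0, seed = 15)
  scan <- simulate_scan(sc, pose(c(4, -6, 0), quat_exp_map(c(0, 0, pi / 2))),
                        lidar_model(range_sigma = 0), seed = NULL)
  img <- label_ground(project_range_image(scan), 10)
  img <- cluster_nonground_bfs(img, min_cluster_size = 30)
  ncl <- max(img$cluster)
  expect_equal(ncl, 2)
  for (k in seq_len(ncl)) {
    truth <- scan$label[img$idx[img$cluster == k]]
    expect_equal(length(unique(truth)), 1)
  }

  # isolated speck below min_cluster_size is discarded
  lid <- lidar_model()
  cells <- data.frame(ring = c(8L, 8L, 8L), col = c(900L, 901L, 902L))
  speck <- cell_scan(cells, c(5, 5, 5))
  img2 <- cluster_nonground_bfs(project_range_image(speck), min_cluster_size = 30)
  expect_true(all(img2$cluster[!is.na(img2$idx)] == -1L))

  # empty image: no clusters
  img3 <- cluster_nonground_bfs(project_range_image(speck[0, ]))
  expect_equal(sum(img3$cluster != 0), 0)
})

test_that("curvature follows the windowed range-difference formula", {
  lid <- lidar_model()
  # straight wall: points along a line have near-zero curvature away from ends
  cells <- data.frame(ring = rep(8L, 101), col = 850:950)
  az <- (cells$col - 0.5) * lid$azimuth_res * pi / 180
  rng <- 5 / cos(az - mean(az))
  scan <- cell_scan(cells, rng)
  img <- project_range_image(scan)
  cv <- compute_curvature(img, half_window = 5)
  expect_lt(max(cv[8 + 1, 860:940], na.rm = TRUE), 1e-3)

  # direct-formula oracle with a depth step at the centre point
  cells2 <- data.frame(ring = rep(4L, 11), col = 101:111)
  rng2 <- rep(5, 11); rng2[6] <- 6  # 1 m step at the centre
  scan2 <- cell_scan(cells2, rng2)
  img2 <- project_range_image(scan2)
  cv2 <- compute_curvature(img2, half_window = 5)
  pts <- cbind(scan2$x, scan2$y, scan2$z)
  i <- 6
  diffsum <- colSums(sweep(pts[setdiff(1:11, i), , drop = FALSE], 2, pts[i, ]))
  oracle <- sqrt(sum(diffsum^2)) / (10 * sqrt(sum(pts[i, ]^2)))
  expect_equal(cv2[5, cells2$col[i]], oracle, tolerance = 1e-12)

  # invariance under rotation about the sensor by a whole number of bins
  sc <- single_tree_scene()
  scan3 <- simulate_scan(sc, pose(), lidar_model(range_sigma = 0), seed = NULL)
  img3 <- project_range_image(scan3)
  cv3 <- compute_curvature(img3)
  rot <- 36  # degrees = 180 columns
  Rz <- quat_to_rotmat(quat_exp_map(c(0, 0, rot * pi / 180)))
  scan4 <- scan3
  xyz <- as.matrix(scan3[, c("x", "y", "z")]) %*% t(Rz)
  scan4$x <- xyz[, 1]; scan4$y <- xyz[, 2]; scan4$z <- xyz[, 3]
  cv4 <- compute_curvature(project_range_image(scan4))
  shifted <- cbind(cv3[, (1800 - 179):1800], cv3[, 1:(1800 - 180)])
  expect_equal(cv4, shifted, tolerance = 1e-9)
})

test_that("feature selection respects the per-sub-image budget", {
  sc <- generate_scene(2, 6, overlap_fraction = 0, seed = 16)
  for (seed in 17:19) {
    scan <- simulate_scan(sc, pose(c(2, 2.5, 0)), lidar_model(), seed = seed)
    img <- label_ground(project_range_image(scan), 10)
    img <- cluster_nonground_bfs(img)
    cv <- compute_curvature(img)
    fs <- select_features(img, cv)
    expect_lte(nrow(fs$sharp), 2 * 6)
    expect_lte(nrow(fs$edge), 20 * 6)
    expect_lte(nrow(fs$flat), 4 * 6)
    expect_lte(nrow(fs$planar), 40 * 6)
    if (nrow(fs$sharp)) expect_true(all(fs$sharp$curvature > 0.1))
    if (nrow(fs$planar)) expect_true(all(fs$planar$curvature < 0.1))
  }
  # sharp edges fall on crown silhouettes
  scan <- simulate_scan(sc, pose(c(2, 2.5, 0)), lidar_model(range_sigma = 0), seed = NULL)
  img <- label_ground(project_range_image(scan), 10)
  img <- cluster_nonground_bfs(img)
  fs <- select_features(img, compute_curvature(img))
  hit <- numeric()
  for (i in seq_len(nrow(fs$sharp))) {
    m <- which(abs(scan$x - fs$sharp$x[i]) < 1e-9 & abs(scan$y - fs$sharp$y[i]) < 1e-9)
    hit <- c(hit, scan$label[m[1]])
  }
  expect_gte(mean(hit > 0), 0.9)
})
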