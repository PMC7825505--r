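test_that("RANSAC recovers exact and contaminated ground planes", {
  # exact horizontal plane
  set.seed(50)
  flat <- data.frame(x = runif(200, -5, 5), y = runif(200, -5, 5), z = 0)
  pl <- fit_ground_plane_ransac(flat, seed = 1)
  expect_equal(pl$coef, c(0, 0, 1, 0), tolerance = 1e-9)
  # three exact points define their unique plane
  tri <- data.frame(x = c(0, 1, 0), y = c(0, 0, 1), z = c(1, 1, 1))
  pl3 <- fit_ground_plane_ransac(tri, seed = 2)
  expect_equal(pl3$coef, c(0, 0, 1, -1), tolerance = 1e-9)
  # 2 cm noise and 10 % outliers a metre up: normal within 1 degree
  n <- 1000
  gp <- data.frame(x = runif(n, -10, 10), y = runif(n, -10, 10),
                   z = rnorm(n, 0, 0.02))
  out <- sample(n, 100)
  gp$z[out] <- gp$z[out] + 1
  pln <- fit_ground_plane_ransac(gp, inlier_threshold = 0.05, seed = 3)
  ang <- acos(abs(pln$coef[3])) * 180 / pi
  expect_lt(ang, 1)
  # deterministic under a fixed seed
  expect_identical(fit_ground_plane_ransac(gp, seed = 3)$coef, pln$coef)
  expect_error(fit_ground_plane_ransac(gp[1:2, ]), "at least 3")
})

test_that("crown height is the maximum signed plane distance", {
  pts <- data.frame(x = runif(50), y = runif(50), z = c(runif(49, 0, 2), 3))
  expect_equal(crown_height(pts, c(0, 0, 1, 0)), 3, tolerance = 1e-12)
  # tilting scene and plane together leaves the height unchanged
  R <- quat_to_rotmat(quat_exp_map(c(0.2, -0.1, 0.3)))
  m <- as.matrix(pts) %*% t(R)
  nrm <- as.numeric(R %*% c(0, 0, 1))
  expect_equal(crown_height(data.frame(x = m[, 1], y = m[, 2], z = m[, 3]),
                            c(nrm, 0)), 3, tolerance = 1e-9)
  expect_error(crown_height(pts[0, ], c(0, 0, 1, 0)), "empty")
})

test_that("alpha-shape volume matches analytic solids", {
  # unit-cube corners with alpha above the circumradius sqrt(3)/2
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 1.0
  av <- alpha_shape_volume(cube, 0.9)
  expect_equal(av$volume, 1, tolerance = 1e-9)
  # alpha below the circumradius keeps nothing
  expect_equal(alpha_shape_volume(cube, 0.5)$volume, 0)
  # coplanar input is rejected
  flat <- cbind(matrix(runif(40), ncol = 2), 0)
  expect_error(alpha_shape_volume(flat, 1), "coplanar")
  # alpha -> infinity equals the convex hull volume (cube corners pin the hull)
  set.seed(51)
  pts <- rbind(cube, matrix(runif(1500, 0.05, 0.95), ncol = 3))
  expect_equal(alpha_shape_volume(pts, 1e6)$volume, 1, tolerance = 1e-6)
})

test_that("alpha-shape volume is monotone in alpha and rigid-invariant", {
  set.seed(52)
  pts <- fill_ellipsoid(2000, 1.2, 0.9)
  vols <- vapply(c(0.1, 0.2, 0.4, 0.8, 2), function(a)
    alpha_shape_volume(pts, a)$volume, numeric(1))
  expect_true(all(diff(vols) >= -1e-12))
  v1 <- alpha_shape_volume(pts, 0.3)$volume
  R <- quat_to_rotmat(quat_exp_map(c(0.4, 0.2, -0.6)))
  moved <- sweep(pts %*% t(R), 2, c(10, -4, 2), "+")
  v2 <- alpha_shape_volume(moved, 0.3)$volume
  expect_equal(v2, v1, tolerance = 1e-6 * v1)
})

test_that("tetrahedralisation agrees with an independent geometric library", {
  set.seed(53)
  pts <- matrix(rnorm(450), ncol = 3)
  total <- alpha_shape_volume(pts, 1e6)$volume
  f <- tempfile(fileext = ".txt")
  write.table(pts, f, row.names = FALSE, col.names = FALSE)
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np; from scipy.spatial import ConvexHull; ",
    "print(ConvexHull(np.loadtxt('", f, "')).volume)"))), stdout = TRUE)
  expect_equal(total, as.numeric(out), tolerance = 1e-6)
})

test_that("reference volumes follow the cone/ellipsoid formulas", {
  expect_equal(reference_volume("cone", 2, 3), pi, tolerance = 1e-12)
  expect_equal(reference_volume("ellipsoid", 2, 3), 2 * pi, tolerance = 1e-12)
  expect_equal(reference_volume("ellipsoid", 1.7, 2.3),
               2 * reference_volume("cone", 1.7, 2.3), tolerance = 1e-12)
  expect_error(reference_volume("cone", -1, 2), "positive")
})

test_that("R^2 and RMSE follow their definitions", {
  x <- c(1, 2, 3, 4.5)
  expect_equal(r2_rmse(x, x), list(r2 = 1, rmse = 0))
  expect_equal(r2_rmse(x, rep(mean(x), 4))$r2, 0, tolerance = 1e-12)
  set.seed(54)
  for (i in 1:5) {
    truth <- rnorm(20); pred <- truth + rnorm(20, 0, 0.3)
    got <- r2_rmse(truth, pred)
    expect_equal(got$r2, 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2),
                 tolerance = 1e-12)
    expect_equal(got$rmse, sqrt(mean((truth - pred)^2)), tolerance = 1e-12)
  }
  expect_error(r2_rmse(c(1, 1), c(1, 2)), "undefined")
})
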