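# shared fixtures and independent oracles

# brute-force connected components of the r-threshold graph (union-find)
brute_components <- function(pts, r) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  D <- as.matrix(stats::dist(pts))
  for (i in seq_len(n - 1))
    for (j in which(D[i, (i + 1):n] <= r) + i)
      { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
  vapply(seq_len(n), find, integer(1))
}

# brute-force SOR removal set per the mean-kNN-distance band
brute_sor <- function(pts, k, m) {
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  md <- apply(D, 1, function(row) mean(sort(row)[1:k]))
  mu <- mean(md); s <- stats::sd(md)
  as.integer(which(md > mu + m * s | md < mu - m * s))
}

# same partition up to relabeling?
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(tapply(b, a, function(x) length(unique(x))) == 1)
}

# a ground-only scene (no trees)
ground_only_scene <- function(sensor_height = 0.8) {
  sc <- generate_scene(1, 1, seed = 1, sensor_height = sensor_height)
  sc$trees <- sc$trees[0, ]
  sc
}

# one-tree scene with chosen crown geometry
single_tree_scene <- function(shape = "ellipsoid", x = 2, y = 2, base = 0.5,
                              cx = 5, cy = 0, sensor_height = 0.8) {
  sc <- generate_scene(1, 1, seed = 1, sensor_height = sensor_height)
  sc$trees$shape <- shape
  sc$trees$x <- x; sc$trees$y <- y
  sc$trees$base_height <- base
  sc$trees$cx <- cx; sc$trees$cy <- cy
  sc
}

# pose error helpers
pos_error <- function(p1, p2) sqrt(sum((p1$t - p2$t)^2))
rot_error_deg <- function(p1, p2) {
  dq <- quat_multiply(quat_conjugate(p1$q), p2$q)
  sqrt(sum(quat_log_map(dq)^2)) * 180 / pi
}

# uniform fill of an ellipsoid solid with semi-axes (a, a, c)
fill_ellipsoid <- function(n, a, c_) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * stats::runif(n)^(1 / 3)
  cbind(a * u[, 1], a * u[, 2], c_ * u[, 3])
}

# the reference orchard cloud used by the segmentation checks: dense crown
# surfaces (map-scale density), no ground, branch bridges between the
# overlap pairs
segmentation_cloud <- function(scene, seed) {
  sample_scene_points(scene, density = 6000, sigma = 0.003, seed = seed,
                      ground_density = 0, interior_fraction = 0)
}
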