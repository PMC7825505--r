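#' Deskew a sweep with the sensor motion over the sweep
#'
#' A spinning LiDAR reports every return in its own instantaneous frame but
#' timestamps them across the 0.1 s sweep, so platform motion smears the
#' scan. Given the relative sensor motion over the sweep (from IMU
#' propagation), each point is re-expressed at the sweep start by applying
#' the fractional transform at its time offset: rotation by spherical
#' interpolation of the quaternion, translation scaled linearly (constant
#' angular and linear velocity over one sweep).
#'
#' A point with `time_offset` 0 is unchanged; a point at the sweep end gets
#' the full motion applied.
#'
#' @param scan scan `data.frame` with a `time_offset` column.
#' @param sweep_transform [pose()]: sensor motion from sweep start to sweep
#'   end, expressed in the sweep-start frame.
#' @param sweep_period sweep duration, seconds.
#' @return the scan with coordinates re-expressed at sweep start.
#' @export
deskew_scan <- function(scan, sweep_transform, sweep_period = 0.1) {
  if (is.null(scan$time_offset)) stop("deskew_scan requires a time_offset column")
  if (max(scan$time_offset) > sweep_period + 1e-9)
    stop("time_offset exceeds the sweep period")
  u_all <- scan$time_offset / sweep_period
  pts <- as_xyz(scan)
  out <- pts
  for (uu in unique(u_all)) {
    sel <- which(u_all == uu)
    q_u <- quat_slerp(quat_identity(), sweep_transform$q, uu)
    out[sel, ] <- sweep(pts[sel, , drop = FALSE] %*% t(quat_to_rotmat(q_u)),
                        2, uu * sweep_transform$t, "+")
  }
  scan$x <- out[, 1]; scan$y <- out[, 2]; scan$z <- out[, 3]
  scan
}

#' Project a sweep into a range image
#'
#' Arranges the sweep as a beams x azimuth-steps grid (16 x 1800 by
#' default): row = ring index, column = `floor(azimuth / resolution)` with
#' azimuth measured counter-clockwise from +x, and cell value the Euclidean
#' range to the sensor. Colliding returns keep the nearer one.
#'
#' @param scan scan `data.frame` with `ring` column, sensor-frame coords.
#' @param lidar the [lidar_model()] describing the grid geometry.
#' @return a `range_image`: list with matrices `range` (NA = empty), `idx`
#'   (row index into the scan), `ground` (logical), `cluster` (0 = none,
#'   -1 = discarded, k >= 1 = cluster id), plus the scan and model.
#' @export
project_range_image <- function(scan, lidar = NULL) {
  lidar <- lidar %||% attr(scan, "lidar") %||% lidar_model()
  if (is.null(scan$ring)) stop("project_range_image requires a ring column")
  nb <- lidar$n_beams; nc <- lidar$azimuth_steps
  az <- atan2(scan$y, scan$x) * 180 / pi
  az <- az %% 360
  col <- pmin(floor(az / lidar$azimuth_res) + 1L, nc)
  row <- as.integer(scan$ring) + 1L
  r <- sqrt(scan$x^2 + scan$y^2 + scan$z^2)
  rng <- matrix(NA_real_, nb, nc)
  idx <- matrix(NA_integer_, nb, nc)
  ord <- order(r, decreasing = TRUE)  # nearer returns overwrite farther ones
  lin <- row[ord] + (col[ord] - 1L) * nb
  rng[lin] <- r[ord]
  idx[lin] <- seq_len(nrow(scan))[ord]
  structure(list(range = rng, idx = idx,
                 ground = matrix(FALSE, nb, nc),
                 cluster = matrix(0L, nb, nc),
                 scan = scan, lidar = lidar), class = "range_image")
}

#' Label ground cells in a range image
#'
#' Walks each column's consecutive lower-beam cell pairs and labels both
#' cells as ground when the elevation angle of the segment joining the two
#' 3D points is below `threshold` degrees -- a near-horizontal step between
#' adjacent rings is ground-like. Only beams pointing below horizontal are
#' eligible.
#'
#' @param image a `range_image`.
#' @param threshold inter-ring elevation-angle threshold, degrees.
#' @return the image with its `ground` matrix filled in.
#' @export
label_ground <- function(image, threshold = 10) {
  lid <- image$lidar
  below <- which(lid$elevations < 0)
  if (length(below) < 2) return(image)
  pts <- as_xyz(image$scan)
  for (k in seq_len(length(below) - 1)) {
    r1 <- below[k]; r2 <- below[k + 1]
    ok <- !is.na(image$idx[r1, ]) & !is.na(image$idx[r2, ])
    if (!any(ok)) next
    p1 <- pts[image$idx[r1, ok], , drop = FALSE]
    p2 <- pts[image$idx[r2, ok], , drop = FALSE]
    d <- p2 - p1
    ang <- atan2(abs(d[, 3]), sqrt(d[, 1]^2 + d[, 2]^2)) * 180 / pi
    g <- ang < threshold
    cols <- which(ok)[g]
    image$ground[r1, cols] <- TRUE
    image$ground[r2, cols] <- TRUE
  }
  image
}

#' Cluster non-ground cells by breadth-first search
#'
#' 4-connected flood fill over the occupied, non-ground cells of the range
#' image (columns wrap around the 360 degree seam). Two neighbouring cells
#' merge when the angle subtended at the sensor between the two returns --
#' `beta = atan2(d2 sin a, d1 - d2 cos a)` with `d1 >= d2` the two ranges
#' and `a` the angular step between the cells -- exceeds `angle_tolerance`:
#' a large beta means the two returns lie on a near-continuous surface.
#' Clusters smaller than `min_cluster_size` are marked discarded (-1).
#'
#' @param image a `range_image` with ground labeled.
#' @param angle_tolerance merge threshold, degrees (default 20: with +/- 2 cm range noise the subtended angle between neighbouring same-surface returns at 10-20 m is marginal at the classical 60 degrees).
#' @param min_cluster_size minimum points per retained cluster.
#' @return the image with its `cluster` matrix filled in.
#' @export
cluster_nonground_bfs <- function(image, angle_tolerance = 20, min_cluster_size = 30) {
  image$cluster <- cpp_range_bfs(image$range, image$ground,
                                 abs(diff(image$lidar$elevations[1:2])) * pi / 180,
                                 image$lidar$azimuth_res * pi / 180,
                                 angle_tolerance * pi / 180,
                                 as.integer(min_cluster_size))
  image
}

#' Per-cell curvature of a range image
#'
#' The smoothness score `c = || sum_{j in S, j != i} (r_j - r_i) || /
#' (|S| * ||r_i||)` over a window `S` of `half_window` consecutive occupied
#' cells on each side of cell `i` within the same ring (columns wrap).
#' Cells without a fully occupied window get `NA`. High curvature marks
#' edges (crown silhouettes), low curvature flat surfaces (ground).
#'
#' @param image a `range_image`.
#' @param half_window cells per side in the window (|S| = 2 * half_window).
#' @return matrix of curvature values (NA where undefined).
#' @export
compute_curvature <- function(image, half_window = 5) {
  nb <- nrow(image$range); nc <- ncol(image$range)
  pts <- as_xyz(image$scan)
  curv <- matrix(NA_real_, nb, nc)
  shifts <- c(-(half_window:1), 1:half_window)
  for (r in seq_len(nb)) {
    occ <- !is.na(image$idx[r, ])
    if (!any(occ)) next
    P <- matrix(NA_real_, nc, 3)
    P[occ, ] <- pts[image$idx[r, occ], , drop = FALSE]
    acc <- matrix(0, nc, 3)
    full <- occ
    for (s in shifts) {
      cols <- ((seq_len(nc) - 1 + s) %% nc) + 1
      full <- full & occ[cols]
      acc <- acc + P[cols, , drop = FALSE]
    }
    n_s <- length(shifts)
    d <- acc - n_s * P
    nrm <- sqrt(rowSums(P^2))
    cv <- sqrt(rowSums(d^2)) / (n_s * nrm)
    curv[r, full] <- cv[full]
  }
  curv
}

#' Select the fixed feature budget from a range image
#'
#' The image is divided into six 60-degree sub-images. In each, cells with
#' curvature above `edge_threshold` are edge candidates (ground cells with
#' high curvature are pooled with them); cells below `plane_threshold` are
#' planar candidates. Per sub-image the budget is 2 sharp edges (maximum
#' curvature) plus up to 20 ordinary edges, and 4 flat planar points
#' (minimum curvature) plus up to 40 ordinary planar points. Picks suppress
#' same-ring neighbours within `suppress` columns so features spread out.
#' Cells of discarded clusters are excluded.
#'
#' @param image a `range_image` (ground labeled, optionally clustered).
#' @param curvature matrix from [compute_curvature()].
#' @param edge_threshold,plane_threshold curvature thresholds.
#' @param suppress neighbour suppression half-width, columns.
#' @return a `feature_set`: data frames `sharp`, `edge`, `flat`, `planar`
#'   (disjoint; sharp/flat are the extreme picks) with point coordinates
#'   and curvature.
#' @export
select_features <- function(image, curvature, edge_threshold = 0.1,
                            plane_threshold = 0.1, suppress = 5) {
  nb <- nrow(image$range); nc <- ncol(image$range)
  pts <- as_xyz(image$scan)
  n_sub <- 6
  sub_w <- nc / n_sub
  res <- list(sharp = NULL, edge = NULL, flat = NULL, planar = NULL)
  cell_df <- function(cells) {
    ridx <- (cells - 1L) %% nb + 1L
    cidx <- (cells - 1L) %/% nb + 1L
    p <- pts[image$idx[cells], , drop = FALSE]
    data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
               ring = ridx - 1L, col = cidx, curvature = curvature[cells],
               ground = image$ground[cells])
  }
  pick <- function(cells, ord, n_top, n_rest) {
    chosen <- integer()
    taken_r <- integer(); taken_c <- integer()
    for (cell in cells[ord]) {
      if (length(chosen) >= n_top + n_rest) break
      r0 <- (cell - 1L) %% nb + 1L
      c0 <- (cell - 1L) %/% nb + 1L
      if (length(taken_r) &&
          any(taken_r == r0 & abs(taken_c - c0) <= suppress)) next
      chosen <- c(chosen, cell)
      taken_r <- c(taken_r, r0); taken_c <- c(taken_c, c0)
    }
    list(top = chosen[seq_len(min(n_top, length(chosen)))],
         rest = if (length(chosen) > n_top) chosen[(n_top + 1):length(chosen)] else integer())
  }
  for (s in seq_len(n_sub)) {
    cols <- ((s - 1) * sub_w + 1):(s * sub_w)
    cells <- which(!is.na(image$idx[, cols, drop = FALSE]) &
                   image$cluster[, cols, drop = FALSE] != -1L &
                   !is.na(curvature[, cols, drop = FALSE]))
    # translate block-local cells to full-image linear indices
    bl_c <- (cells - 1L) %/% nb + 1L
    cells <- ((cols[bl_c] - 1L) * nb) + ((cells - 1L) %% nb + 1L)
    if (!length(cells)) next
    cv <- curvature[cells]
    ec <- cells[cv > edge_threshold]
    e <- pick(ec, order(curvature[ec], decreasing = TRUE), 2, 20)
    pc <- cells[cv < plane_threshold]
    pc <- setdiff(pc, c(e$top, e$rest))
    p <- pick(pc, order(curvature[pc]), 4, 40)
    res$sharp <- rbind(res$sharp, if (length(e$top)) cell_df(e$top))
    res$edge <- rbind(res$edge, if (length(e$rest)) cell_df(e$rest))
    res$flat <- rbind(res$flat, if (length(p$top)) cell_df(p$top))
    res$planar <- rbind(res$planar, if (length(p$rest)) cell_df(p$rest))
  }
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      ring = integer(), col = integer(), curvature = numeric(),
                      ground = logical())
  for (nm in names(res)) if (is.null(res[[nm]])) res[[nm]] <- empty
  structure(res, class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("feature set:", nrow(x$sharp), "sharp +", nrow(x$edge), "edge,",
      nrow(x$flat), "flat +", nrow(x$planar), "planar\n")
  invisible(x)
}

# edge / planar points of a feature set as matrices (sharp and flat included)
feature_points <- function(fs, what = c("edge", "planar")) {
  what <- match.arg(what)
  if (what == "edge") as_xyz(rbind(fs$sharp, fs$edge))
  else as_xyz(rbind(fs$flat, fs$planar))
}

# full preprocessing of one (already deskewed) scan
preprocess_scan <- function(scan, lidar, cfg = list()) {
  img <- project_range_image(scan, lidar)
  img <- label_ground(img, threshold = cfg$ground_angle %||% 10)
  img <- cluster_nonground_bfs(img,
                               angle_tolerance = cfg$cluster_angle %||% 20,
                               min_cluster_size = cfg$min_cluster_size %||% 30)
  curv <- compute_curvature(img, half_window = cfg$half_window %||% 5)
  select_features(img, curv,
                  edge_threshold = cfg$edge_threshold %||% 0.1,
                  plane_threshold = cfg$plane_threshold %||% 0.1)
}
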