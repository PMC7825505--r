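#' RANSAC ground-plane fit
#'
#' Repeatedly fits planes through random point triples, keeps the plane
#' with the most inliers within `inlier_threshold`, then refines it by a
#' total-least-squares fit (centroid + smallest-eigenvector normal) on the
#' inliers. The normal is oriented with positive z.
#'
#' @param cloud ground point cloud (at least 3 non-collinear points).
#' @param inlier_threshold inlier distance, metres.
#' @param max_iter RANSAC iterations.
#' @param seed RNG seed (fit is deterministic for a fixed seed).
#' @return a `ground_plane`: unit coefficients `(a, b, c, d)` of
#'   `ax + by + cz + d = 0` with `c > 0`, inlier indices and the threshold.
#' @export
fit_ground_plane_ransac <- function(cloud, inlier_threshold = 0.05,
                                    max_iter = 500, seed = 1) {
  pts <- as_xyz(cloud)
  n <- nrow(pts)
  if (n < 3) stop("ground-plane fit needs at least 3 points")
  with_seed(seed, {
    best <- NULL; best_n <- -1L
    for (it in seq_len(max_iter)) {
      tri <- sample.int(n, 3)
      u <- pts[tri[2], ] - pts[tri[1], ]
      v <- pts[tri[3], ] - pts[tri[1], ]
      nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
      nl <- sqrt(sum(nrm^2))
      if (nl < 1e-12) next
      nrm <- nrm / nl
      d0 <- -sum(nrm * pts[tri[1], ])
      ninl <- sum(abs(pts %*% nrm + d0) <= inlier_threshold)
      if (ninl > best_n) { best_n <- ninl; best <- c(nrm, d0) }
    }
    if (is.null(best)) stop("degenerate ground cloud: all samples collinear")
    inl <- which(abs(pts %*% best[1:3] + best[4]) <= inlier_threshold)
    if (length(inl) >= 3) {
      P <- pts[inl, , drop = FALSE]
      ctr <- colMeans(P)
      ev <- eigen(crossprod(sweep(P, 2, ctr)), symmetric = TRUE)
      if (ev$values[1] - ev$values[3] > 1e-12 * max(ev$values[1], 1)) {
        nrm <- ev$vectors[, 3]
        best <- c(nrm, -sum(nrm * ctr))
        inl <- which(abs(pts %*% best[1:3] + best[4]) <= inlier_threshold)
      }
    }
    if (best[3] < 0) best <- -best
    if (abs(best[3]) < 1e-12) stop("degenerate ground cloud: vertical fit")
    structure(list(coef = best, inliers = inl, threshold = inlier_threshold,
                   seed = seed), class = "ground_plane")
  })
}

#' Crown height of a segmented tree
#'
#' The maximum signed point-to-plane distance of the tree's points above
#' the fitted ground plane (signed with the plane's upward normal, never
#' clamped).
#'
#' @param tree tree point cloud (or a `tree_instance` plus the source
#'   cloud's points as `cloud`).
#' @param plane a `ground_plane` (or length-4 coefficient vector).
#' @param cloud source cloud when `tree` is a `tree_instance`.
#' @return crown height, metres.
#' @export
crown_height <- function(tree, plane, cloud = NULL) {
  pts <- if (inherits(tree, "tree_instance")) {
    if (is.null(cloud)) stop("supply the source cloud for a tree_instance")
    as_xyz(cloud)[tree$points, , drop = FALSE]
  } else as_xyz(tree)
  if (nrow(pts) == 0) stop("empty tree")
  cf <- if (inherits(plane, "ground_plane")) plane$coef else plane
  max(pts %*% cf[1:3] + cf[4])
}

#' Alpha-shape crown volume
#'
#' Computes the 3D Delaunay tetrahedralisation of the crown points, keeps
#' the tetrahedra whose circumscribed sphere has radius at most `alpha`
#' (the alpha complex -- the "roller radius" picture of the alpha shape),
#' and sums their volumes `V = (1/3) A h` (evaluated by the determinant
#' formula). The result is monotone non-decreasing in `alpha` and converges
#' to the convex-hull volume as `alpha` grows.
#'
#' @param tree_points at least 4 affinely independent points.
#' @param alpha roller radius, metres (default operating point 0.25 m).
#' @return list `(volume, n_tet)`: crown volume (m^3) and the number of
#'   retained tetrahedra.
#' @export
alpha_shape_volume <- function(tree_points, alpha) {
  stopifnot(alpha > 0)
  pts <- as_xyz(tree_points)
  if (nrow(pts) < 4) stop("alpha shape needs at least 4 points")
  sv <- svd(sweep(pts, 2, colMeans(pts)))$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("degenerate geometry: points are (near-)coplanar")
  dl <- cpp_delaunay3d(pts)
  keep <- dl$circumradius <= alpha
  list(volume = sum(dl$volume[keep]), n_tet = sum(keep))
}

#' Reference crown volume from tape measurements
#'
#' The geometric reference volumes used for manual validation:
#' `V = pi x^2 y / 12` for a conical crown and `V = pi x^2 y / 6` for an
#' ellipsoidal crown, with `x` the crown diameter and `y` the crown height
#' (both in metres). These are the exact solid volumes of a cone of base
#' diameter `x` and an ellipsoid of axes `x`, `x`, `y`.
#'
#' @param shape `"cone"` or `"ellipsoid"`.
#' @param x crown diameter, metres.
#' @param y crown height, metres.
#' @return volume, m^3.
#' @export
reference_volume <- function(shape = c("cone", "ellipsoid"), x, y) {
  shape <- match.arg(shape)
  if (any(x <= 0) || any(y <= 0)) stop("crown dimensions must be positive")
  if (shape == "cone") pi * x^2 * y / 12 else pi * x^2 * y / 6
}

#' Coefficient of determination and root-mean-square error
#'
#' `R^2 = 1 - SS_res / SS_tot` and `RMSE = sqrt(mean((y - yhat)^2))`
#' between reference and predicted values. Equal vectors give exactly
#' `(1, 0)`; zero total variance with non-zero residuals is signalled as an
#' error (R^2 undefined).
#'
#' @param truth,pred equal-length numeric vectors.
#' @return list `(r2, rmse)`.
#' @export
r2_rmse <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  ss_res <- sum((truth - pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) {
    if (ss_res == 0) return(list(r2 = 1, rmse = 0))
    stop("R^2 undefined: zero total variance with non-zero residuals")
  }
  list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(mean((truth - pred)^2)))
}

#' Per-tree canopy metrics table
#'
#' @param instances list of `tree_instance`s.
#' @param cloud the segmented source cloud.
#' @param plane a `ground_plane`.
#' @param alpha alpha-shape roller radius, metres.
#' @param max_points_per_tree optional per-tree subsample cap for the
#'   tetrahedralisation.
#' @return data.frame `(id, n_points, height_m, volume_m3, n_tet, alpha)`.
#' @export
canopy_metrics_table <- function(instances, cloud, plane, alpha = 0.25,
                                 max_points_per_tree = 20000) {
  pts <- as_xyz(cloud)
  rows <- lapply(instances, function(inst) {
    p <- pts[inst$points, , drop = FALSE]
    h <- crown_height(p, plane)
    if (nrow(p) > max_points_per_tree)
      p <- p[round(seq(1, nrow(p), length.out = max_points_per_tree)), , drop = FALSE]
    av <- tryCatch(alpha_shape_volume(p, alpha), error = function(e) list(volume = NA_real_, n_tet = NA_integer_))
    data.frame(id = inst$id, n_points = length(inst$points), height_m = h,
               volume_m3 = av$volume, n_tet = av$n_tet, alpha = alpha)
  })
  do.call(rbind, rows)
}
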