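#' Euclidean clustering
#'
#' Groups points into the connected components of the graph linking every
#' pair of points within `radius` of each other (the classical k-d-tree
#' flood-fill segmentation); components smaller than `min_size` are
#' discarded. The result is independent of point order up to relabeling --
#' clusters are reported in order of their first member point.
#'
#' @param cloud point cloud (`data.frame` or matrix).
#' @param radius clustering distance threshold, metres (20 mm is the
#'   operating point for assembled orchard maps).
#' @param min_size minimum cluster size.
#' @return list with `clusters` (list of row-index vectors) and `discarded`
#'   (row indices of sub-threshold components).
#' @export
euclidean_cluster <- function(cloud, radius, min_size = 1) {
  stopifnot(radius > 0)
  pts <- as_xyz(cloud)
  if (nrow(pts) == 0) return(list(clusters = list(), discarded = integer()))
  lab <- cpp_radius_components(pts, radius)
  sizes <- tabulate(lab)
  keep_ids <- which(sizes >= min_size)
  clusters <- unname(split(seq_len(nrow(pts)), lab))
  discarded <- unlist(clusters[setdiff(seq_along(clusters), keep_ids)], use.names = FALSE)
  clusters <- clusters[keep_ids]
  # deterministic order: by first member index
  if (length(clusters))
    clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
  list(clusters = clusters, discarded = sort(discarded %||% integer()))
}

#' Should a cluster be segmented a second time?
#'
#' Connected canopies survive the first clustering pass as one oversized
#' cluster. A cluster is flagged when its point count exceeds
#' `count_factor` times the median first-pass cluster size AND its
#' horizontal extent exceeds `extent_factor` times the in-row tree spacing
#' -- a single crown fits inside one spacing, two joined crowns do not.
#'
#' @param cluster_points the cluster's points.
#' @param bounds list with `max_points` and `max_extent` (see
#'   [second_pass_bounds()]).
#' @return `TRUE` if the cluster needs the SOR-based second pass.
#' @export
needs_second_pass <- function(cluster_points, bounds) {
  pts <- as_xyz(cluster_points)
  extent <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  nrow(pts) > bounds$max_points && extent > bounds$max_extent
}

#' @rdname needs_second_pass
#' @param clusters list of cluster point sets (or sizes).
#' @param in_row_spacing in-row tree spacing, metres.
#' @param count_factor,extent_factor flag thresholds.
#' @export
second_pass_bounds <- function(clusters, in_row_spacing,
                               count_factor = 1.8, extent_factor = 1.2) {
  sizes <- vapply(clusters, function(cl) if (is.numeric(cl) && length(cl) == 1) cl else nrow(as_xyz(cl)), numeric(1))
  # with fewer than 3 clusters the median is not a single-tree reference;
  # fall back to the extent criterion alone
  list(max_points = if (length(sizes) >= 3) count_factor * stats::median(sizes) else 0,
       max_extent = extent_factor * in_row_spacing)
}

#' Statistical outlier removal
#'
#' For every point the mean distance to its `k` nearest neighbours is
#' computed; `mu` and `sigma` are the mean and standard deviation of these
#' per-point means over the whole cloud. Points whose mean distance falls
#' outside `[mu - m sigma, mu + m sigma]` (strictly) are removed. On a
#' perfectly uniform grid every per-point mean is equal, so nothing is
#' removed for any positive `m`. The removal set depends only on inter-point
#' distances, hence is invariant under rigid transforms.
#'
#' @param cloud point cloud with more than `k` points.
#' @param k neighbour count (default operating point 50).
#' @param m standard-deviation multiplier (default operating point 0.01).
#' @return list with `kept`/`removed` row indices, the per-point mean
#'   distances `mean_dist`, and `mu`, `sigma`.
#' @export
sor_filter <- function(cloud, k = 50, m = 0.01) {
  stopifnot(k >= 1, m > 0)
  pts <- as_xyz(cloud)
  if (nrow(pts) <= k) stop("SOR needs more than k points (", nrow(pts), " <= ", k, ")")
  d <- cpp_mean_knn_dist(pts, k)
  mu <- mean(d)
  sigma <- stats::sd(d)
  # guard band at float precision: on exactly degenerate distributions
  # (all per-point means equal) summation rounding must not eject points
  tol <- 1e-12 * (abs(mu) + 1)
  removed <- which(d > mu + m * sigma + tol | d < mu - m * sigma - tol)
  list(kept = setdiff(seq_len(nrow(pts)), removed), removed = removed,
       mean_dist = d, mu = mu, sigma = sigma)
}

#' Reassign filtered points to their nearest cluster
#'
#' Every removed point joins the cluster of its nearest kept point (k = 1
#' nearest-neighbour recovery). Exact distance ties go to the lowest
#' cluster id.
#'
#' @param removed_pts points to reassign (matrix or data.frame).
#' @param kept_pts kept points (matrix or data.frame).
#' @param kept_labels cluster id of each kept point.
#' @return integer vector: cluster id per removed point.
#' @export
knn_reassign <- function(removed_pts, kept_pts, kept_labels) {
  rp <- as_xyz(removed_pts); kp <- as_xyz(kept_pts)
  if (nrow(kp) == 0 || length(unique(kept_labels)) == 0)
    stop("knn_reassign requires at least one non-empty cluster")
  if (nrow(rp) == 0) return(integer())
  kq <- min(4, nrow(kp))
  nn <- cpp_knn(kp, rp, k = kq)
  out <- integer(nrow(rp))
  for (i in seq_len(nrow(rp))) {
    dmin <- nn$dist[i, 1]
    tied <- nn$idx[i, nn$dist[i, ] <= dmin + 1e-12]
    out[i] <- min(kept_labels[tied])
  }
  out
}

#' Two-step segmentation of an orchard map into individual trees
#'
#' Pass 1 is Euclidean clustering of the non-ground cloud. Clusters flagged
#' as containing joined canopies ([needs_second_pass()]) are re-segmented:
#' SOR filtering strips the scattered inter-crown points and thins the
#' cloud to its density-typical core, the core is re-clustered at a coarser
#' radius suited to the thinned cloud, and every filtered point is restored
#' to its nearest core cluster by [knn_reassign()]. Second-pass fragments
#' below `second_min_size` join the recovery pool too.
#'
#' @param cloud non-ground point cloud.
#' @param radius,min_size first-pass clustering parameters.
#' @param k,m SOR parameters.
#' @param in_row_spacing in-row tree spacing (for the oversize flag).
#' @param second_radius second-pass clustering radius (metres) applied to
#'   the SOR-thinned core.
#' @param second_min_size minimum second-pass cluster size.
#' @return list of `tree_instance`s: each has `points` (row indices into
#'   `cloud`), `provenance` (`"first-pass"`, `"second-pass"`,
#'   `"knn-recovered"`) and a bounding box; plus attribute `"discarded"`
#'   with the indices dropped as sub-threshold first-pass components.
#' @export
segment_trees <- function(cloud, radius = 0.02, min_size = 50, k = 50, m = 0.01,
                          in_row_spacing = 4, second_radius = 0.25,
                          second_min_size = 30) {
  pts <- as_xyz(cloud)
  ec <- euclidean_cluster(cloud, radius, min_size)
  bounds <- second_pass_bounds(lapply(ec$clusters, length), in_row_spacing)
  instances <- list()
  for (ci in seq_along(ec$clusters)) {
    idx <- ec$clusters[[ci]]
    sub <- pts[idx, , drop = FALSE]
    if (!needs_second_pass(sub, bounds) || length(idx) <= k) {
      instances[[length(instances) + 1]] <-
        list(points = idx, provenance = rep("first-pass", length(idx)))
      next
    }
    sf <- sor_filter(sub, k = k, m = m)
    core <- euclidean_cluster(sub[sf$kept, , drop = FALSE], second_radius,
                              min_size = second_min_size)
    if (length(core$clusters) == 0) {
      # SOR left no usable core: keep the cluster whole
      instances[[length(instances) + 1]] <-
        list(points = idx, provenance = rep("first-pass", length(idx)))
      next
    }
    kept_idx <- sf$kept
    core_labels <- integer(length(kept_idx))
    for (j in seq_along(core$clusters)) core_labels[core$clusters[[j]]] <- j
    pool <- c(sf$removed, kept_idx[core_labels == 0])
    core_keep <- kept_idx[core_labels > 0]
    lab_keep <- core_labels[core_labels > 0]
    assigned <- if (length(pool))
      knn_reassign(sub[pool, , drop = FALSE], sub[core_keep, , drop = FALSE], lab_keep)
    else integer()
    for (j in seq_along(core$clusters)) {
      members_core <- idx[core_keep[lab_keep == j]]
      members_rec <- idx[pool[assigned == j]]
      instances[[length(instances) + 1]] <- list(
        points = c(members_core, members_rec),
        provenance = c(rep("second-pass", length(members_core)),
                       rep("knn-recovered", length(members_rec))))
    }
  }
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    p <- pts[inst$points, , drop = FALSE]
    instances[[i]] <- structure(list(id = i, points = inst$points,
                                     provenance = inst$provenance,
                                     bbox = apply(p, 2, range)),
                                class = "tree_instance")
  }
  attr(instances, "discarded") <- ec$discarded
  instances
}

#' Segmentation success against ground truth
#'
#' A truth tree counts as a success iff exactly one instance claims the
#' majority of its points and that instance's own majority label is that
#' tree; merged or split trees count as failures. The rate is successes
#' over truth trees.
#'
#' @param instances list of `tree_instance`s from [segment_trees()].
#' @param truth integer truth label per row of the segmented cloud
#'   (tree ids > 0; 0 = ground/none).
#' @return list `(successes, failures, rate, per_tree)`.
#' @export
evaluate_segmentation <- function(instances, truth) {
  trees <- sort(unique(truth[truth > 0]))
  inst_of <- rep(NA_integer_, length(truth))
  for (inst in instances) inst_of[inst$points] <- inst$id
  # majority label of each instance
  inst_major <- vapply(instances, function(inst) {
    tl <- truth[inst$points]
    tl <- tl[tl > 0]
    if (!length(tl)) return(NA_integer_)
    as.integer(names(which.max(table(tl))))
  }, integer(1))
  per <- data.frame(tree = trees, success = FALSE)
  for (ti in seq_along(trees)) {
    tr <- trees[ti]
    rows <- which(truth == tr)
    io <- inst_of[rows]
    io <- io[!is.na(io)]
    if (!length(io)) next
    tab <- table(io)
    claimer <- as.integer(names(which.max(tab)))
    if (max(tab) <= length(rows) / 2) next          # no instance holds a majority
    per$success[ti] <- identical(inst_major[claimer], tr)
  }
  # an instance can "win" several trees (merged canopy): those trees all
  # fail the one-to-one criterion
  winners <- integer()
  for (ti in seq_along(trees)) {
    rows <- which(truth == trees[ti])
    io <- inst_of[rows]; io <- io[!is.na(io)]
    if (!length(io)) { winners <- c(winners, NA_integer_); next }
    winners <- c(winners, as.integer(names(which.max(table(io)))))
  }
  dup <- winners[duplicated(winners) & !is.na(winners)]
  per$success[winners %in% dup] <- FALSE
  s <- sum(per$success)
  list(successes = s, failures = length(trees) - s,
       rate = s / length(trees), per_tree = per)
}
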