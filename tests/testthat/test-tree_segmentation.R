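test_that("Euclidean clustering equals connected components of the r-graph", {
  # the 20 mm operating threshold on constructed points
  two <- data.frame(x = c(0, 0.001), y = 0, z = 0)
  ec <- euclidean_cluster(two, 0.02)
  expect_equal(length(ec$clusters), 1)
  apart <- data.frame(x = c(0, 0.03), y = 0, z = 0)
  ec2 <- euclidean_cluster(apart, 0.02)
  expect_equal(length(ec2$clusters), 2)

  # union-find oracle on random clouds
  set.seed(40)
  for (rep in 1:5) {
    pts <- matrix(runif(3 * 300, 0, 1.2), ncol = 3)
    r <- runif(1, 0.05, 0.2)
    ec <- euclidean_cluster(pts, r)
    lab <- integer(nrow(pts))
    for (j in seq_along(ec$clusters)) lab[ec$clusters[[j]]] <- j
    expect_true(same_partition(lab, brute_components(pts, r)))
  }

  # empty input
  expect_equal(euclidean_cluster(data.frame(x = numeric(), y = numeric(),
                                            z = numeric()), 0.1)$clusters, list())
})

test_that("oversize flags fire exactly on joined canopies", {
  sizes <- list(1000, 1100, 900, 2500)
  b <- second_pass_bounds(sizes, in_row_spacing = 4)
  wide <- matrix(c(runif(3000, 0, 8), runif(3000, 0, 2), runif(3000, 0, 3)), ncol = 3)
  expect_true(needs_second_pass(wide[1:2500, ], b))
  narrow <- matrix(runif(900 * 3, 0, 3.4), ncol = 3)
  expect_false(needs_second_pass(narrow, b))

  # truth oracle: flags raised exactly on clusters holding >= 2 trees
  sc <- generate_scene(1, 4, overlap_fraction = 0.5, seed = 41)
  cl <- segmentation_cloud(sc, seed = 42)
  ec <- euclidean_cluster(cl, 0.02, 50)
  bounds <- second_pass_bounds(lapply(ec$clusters, length), 4)
  for (cluster in ec$clusters) {
    n_trees <- length(unique(cl$label[cluster]))
    flagged <- needs_second_pass(cl[cluster, ], bounds)
    expect_equal(flagged, n_trees >= 2)
  }
})

test_that("SOR matches its brute-force definition and respects invariants", {
  set.seed(43)
  # brute-force oracle on random clouds
  for (rep in 1:5) {
    pts <- matrix(rnorm(3 * 150), ncol = 3)
    k <- sample(5:20, 1); m <- runif(1, 0.2, 1.5)
    sf <- sor_filter(pts, k = k, m = m)
    expect_equal(sort(sf$removed), sort(brute_sor(pts, k, m)))
    # rigid-transform invariance of the removal set
    R <- quat_to_rotmat(quat_normalize(rnorm(4)))
    moved <- sweep(pts %*% t(R), 2, rnorm(3, 0, 5), "+")
    expect_equal(sort(sor_filter(moved, k = k, m = m)$removed), sort(sf$removed))
  }
  # a uniform grid loses nothing for any positive m (k = 3: all per-point
  # means equal even at the boundary)
  g <- as.matrix(expand.grid(x = 1:8, y = 1:8, z = 1:4)) * 0.1
  expect_equal(length(sor_filter(g, k = 3, m = 0.001)$removed), 0)
  expect_error(sor_filter(g[1:5, ], k = 10), "more than k")
})

test_that("SOR at the reference operating point strips the inter-crown bridge", {
  sc <- generate_scene(1, 2, overlap_fraction = 1, seed = 3)
  cl <- segmentation_cloud(sc, seed = 4)
  ec <- euclidean_cluster(cl, 0.02, 50)
  big <- ec$clusters[[which.max(sapply(ec$clusters, length))]]
  expect_equal(length(unique(cl$label[big])), 2)  # the pair is joined
  sub <- cl[big, ]
  sf <- sor_filter(sub, k = 50, m = 0.01)
  core <- euclidean_cluster(sub[sf$kept, , drop = FALSE], 0.25, 30)
  expect_equal(length(core$clusters), 2)
  purity <- vapply(core$clusters, function(cc) {
    tl <- sub$label[sf$kept[cc]]
    max(table(tl)) / length(tl)
  }, numeric(1))
  expect_true(all(purity > 0.95))
})

test_that("KNN recovery reassigns to the nearest cluster with a documented tie-break", {
  kept <- data.frame(x = c(-1, 1, 5), y = 0, z = 0)
  labs <- c(2L, 1L, 3L)
  # clear nearest
  expect_equal(knn_reassign(data.frame(x = 0.9, y = 0.01, z = 0), kept, labs), 1L)
  # exact tie between clusters 1 and 2 -> lowest id wins
  expect_equal(knn_reassign(data.frame(x = 0, y = 0, z = 0), kept, labs), 1L)
  expect_error(knn_reassign(data.frame(x = 0, y = 0, z = 0), kept[0, ], integer()),
               "non-empty")
})

test_that("two-step segmentation conserves points and is deterministic", {
  sc <- generate_scene(1, 3, overlap_fraction = 0.5, seed = 44)
  cl <- segmentation_cloud(sc, seed = 45)
  inst <- segment_trees(cl, radius = 0.02, min_size = 50, k = 50, m = 0.01,
                        in_row_spacing = 4)
  claimed <- unlist(lapply(inst, `[[`, "points"))
  expect_equal(length(claimed), length(unique(claimed)))  # disjoint
  expect_equal(length(claimed) + length(attr(inst, "discarded")), nrow(cl))
  # recovery accuracy of the reassigned points
  rec_ok <- ok_all <- 0
  for (x in inst) {
    rec <- x$points[x$provenance == "knn-recovered"]
    if (!length(rec)) next
    maj <- as.integer(names(which.max(table(cl$label[x$points]))))
    rec_ok <- rec_ok + sum(cl$label[rec] == maj)
    ok_all <- ok_all + length(rec)
  }
  if (ok_all > 0) expect_gte(rec_ok / ok_all, 0.95)
  # determinism up to relabeling
  inst2 <- segment_trees(cl, radius = 0.02, min_size = 50, k = 50, m = 0.01,
                         in_row_spacing = 4)
  expect_identical(lapply(inst, `[[`, "points"), lapply(inst2, `[[`, "points"))
})

test_that("isolated trees segment in one pass", {
  sc <- generate_scene(1, 3, overlap_fraction = 0, seed = 46)
  cl <- segmentation_cloud(sc, seed = 47)
  inst <- segment_trees(cl, radius = 0.02, min_size = 50, k = 50, m = 0.01,
                        in_row_spacing = 4)
  expect_equal(length(inst), 3)
  expect_true(all(unlist(lapply(inst, `[[`, "provenance")) == "first-pass"))
})

test_that("segmentation evaluation implements the one-to-one majority rule", {
  truth <- c(rep(1L, 10), rep(2L, 10), rep(3L, 4))
  mk <- function(id, pts) structure(list(id = id, points = pts), class = "tree_instance")
  # perfect segmentation
  perfect <- list(mk(1L, 1:10), mk(2L, 11:20), mk(3L, 21:24))
  ev <- evaluate_segmentation(perfect, truth)
  expect_equal(ev$rate, 1)
  # two trees merged into one instance: both fail
  merged <- list(mk(1L, 1:20), mk(2L, 21:24))
  ev2 <- evaluate_segmentation(merged, truth)
  expect_equal(ev2$successes, 1)
  expect_false(ev2$per_tree$success[1])
  expect_false(ev2$per_tree$success[2])
  # a split tree fails: majority instance majority-labels elsewhere?
  split_ <- list(mk(1L, 1:5), mk(2L, 6:10), mk(3L, 11:20), mk(4L, 21:24))
  ev3 <- evaluate_segmentation(split_, truth)
  # tree 1's majority claimer holds only 5/10 <= half -> failure
  expect_false(ev3$per_tree$success[1])
  expect_true(ev3$per_tree$success[2])
})
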