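#' Run the orchard phenotyping pipeline
#'
#' Orchestrates the stages end-to-end with a single configuration and
#' deterministic seeds; stages communicate only through files in `out_dir`
#' so each is independently inspectable and resumable:
#'
#' * `simulate` -- scene truth tables, the dense labeled map-scale cloud,
#'   trajectory + IMU CSVs and a set of motion-distorted sweeps (PCD).
#' * `map` -- LiDAR-inertial odometry over the sweeps, the assembled
#'   voxel-downsampled map, and its ground / non-ground partition.
#' * `segment` -- two-step tree segmentation (one PCD per tree + manifest).
#' * `measure` -- RANSAC ground plane, per-tree crown height and
#'   alpha-shape volume CSV.
#' * `evaluate` -- segmentation success rate and height/volume agreement
#'   with scene truth.
#' * `sweep` -- re-runs segmentation + evaluation over a grid of SOR
#'   multipliers `m` and writes a success-rate table.
#' * `all` -- simulate through evaluate.
#'
#' The global seed fans out to fixed per-stage offsets (+1 scene, +2
#' sampling, +3 trajectory, +4 scans, +5 metrics), recorded in each stage's
#' manifest next to the configuration hash.
#'
#' @param subcommand one of `simulate`, `map`, `segment`, `measure`,
#'   `evaluate`, `sweep`, `all`.
#' @param config configuration list (see [default_config()]) or a YAML
#'   path.
#' @param out_dir output directory (created if missing).
#' @param seed optional override of `config$seed`.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "map", "segment",
                                        "measure", "evaluate", "sweep"),
                         config = default_config(), out_dir, seed = NULL) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- load_config(config)
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  steps <- if (subcommand == "all") c("simulate", "map", "segment", "measure", "evaluate")
           else subcommand
  arts <- list()
  for (s in steps) {
    arts <- c(arts, switch(s,
      simulate = stage_simulate(config, out_dir),
      map = stage_map(config, out_dir),
      segment = stage_segment(config, out_dir),
      measure = stage_measure(config, out_dir),
      evaluate = stage_evaluate(config, out_dir),
      sweep = stage_sweep(config, out_dir)))
  }
  invisible(arts)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

write_manifest <- function(cfg, out_dir, stage, extra = list()) {
  man <- c(list(stage = stage, config_hash = config_hash(cfg), seed = cfg$seed,
                package_version = as.character(utils::packageVersion("orchardcanopy"))),
           extra)
  path <- file.path(out_dir, paste0("manifest_", stage, ".yaml"))
  yaml::write_yaml(man, path)
  path
}

scene_from_config <- function(cfg) {
  generate_scene(n_rows = cfg$scene$n_rows, trees_per_row = cfg$scene$trees_per_row,
                 overlap_fraction = cfg$scene$overlap_fraction, seed = cfg$seed + 1,
                 row_spacing = cfg$scene$row_spacing,
                 in_row_spacing = cfg$scene$in_row_spacing,
                 sensor_height = cfg$sensor$mount_height)
}

lidar_from_config <- function(cfg) {
  do.call(lidar_model, cfg$sensor$lidar)
}

stage_simulate <- function(cfg, out_dir) {
  scene <- scene_from_config(cfg)
  lidar <- lidar_from_config(cfg)
  utils::write.csv(scene$trees, file.path(out_dir, "scene_trees.csv"), row.names = FALSE)
  yaml::write_yaml(list(ground = as.numeric(scene$ground),
                        sensor_height = scene$sensor_height,
                        row_spacing = scene$row_spacing,
                        in_row_spacing = scene$in_row_spacing,
                        overlap_pairs = as.list(scene$overlap_pairs)),
                   file.path(out_dir, "scene_meta.yaml"))
  cloud <- sample_scene_points(scene, density = cfg$scene$density,
                               sigma = cfg$scene$noise_sigma, seed = cfg$seed + 2,
                               ground_density = cfg$scene$ground_density,
                               interior_fraction = cfg$scene$interior_fraction,
                               bridge_points = cfg$scene$bridge_points)
  write_point_cloud(cloud, file.path(out_dir, "map_points.pcd"))
  imu_m <- imu_model(rate = cfg$sensor$imu$rate,
                     gyro_noise = cfg$sensor$imu$gyro_noise,
                     accel_noise = cfg$sensor$imu$accel_noise)
  sim <- simulate_trajectory(scene, speed = cfg$simulate$speed, seed = cfg$seed + 3,
                             imu = imu_m, static_time = cfg$simulate$static_time,
                             pitch_amp = cfg$simulate$pitch_amp,
                             roll_amp = cfg$simulate$roll_amp)
  write_trajectory(sim$trajectory, file.path(out_dir, "trajectory_truth.csv"))
  write_imu(sim$imu, file.path(out_dir, "imu.csv"))
  period <- 1 / lidar$sweep_rate
  t0 <- cfg$simulate$static_time
  times <- t0 + (seq_len(cfg$simulate$n_sweeps) - 1) * period
  times <- times[times <= max(sim$trajectory$timestamp) - period]
  scan_dir <- file.path(out_dir, "scans")
  dir.create(scan_dir, showWarnings = FALSE)
  scans <- simulate_sweep_sequence(scene, sim$trajectory, lidar, times = times,
                                   seed = cfg$seed + 4)
  for (i in seq_along(scans))
    write_point_cloud(scans[[i]], file.path(scan_dir, sprintf("scan_%04d.pcd", i)))
  utils::write.csv(data.frame(scan = seq_along(scans), time = times),
                   file.path(out_dir, "scan_times.csv"), row.names = FALSE)
  write_manifest(cfg, out_dir, "simulate",
                 list(n_scans = length(scans), n_map_points = nrow(cloud)))
  list(scene = file.path(out_dir, "scene_trees.csv"),
       map_points = file.path(out_dir, "map_points.pcd"),
       scans = scan_dir)
}

stage_map <- function(cfg, out_dir) {
  lidar <- lidar_from_config(cfg)
  st <- utils::read.csv(file.path(out_dir, "scan_times.csv"))
  scans <- lapply(st$scan, function(i)
    read_point_cloud(file.path(out_dir, "scans", sprintf("scan_%04d.pcd", i))))
  imu <- read_imu(file.path(out_dir, "imu.csv"))
  od <- run_odometry(scans, imu, lidar, sweep_times = st$time,
                     init_window = cfg$odometry$init_window,
                     config = c(cfg$preprocess, cfg$odometry))
  write_trajectory(od$trajectory, file.path(out_dir, "odometry.csv"))
  utils::write.csv(od$diagnostics, file.path(out_dir, "odometry_diagnostics.csv"),
                   row.names = FALSE)
  poses <- lapply(seq_len(nrow(od$trajectory)), function(i) {
    r <- od$trajectory[i, ]
    pose(c(r$tx, r$ty, r$tz), c(r$qw, r$qx, r$qy, r$qz))
  })
  map <- assemble_map(scans, poses, voxel_size = cfg$mapping$voxel_size)
  mp <- xyz_df(map$points)
  write_point_cloud(mp, file.path(out_dir, "map.pcd"))
  gp <- remove_ground_by_sensor_height(mp, cfg$sensor$mount_height)
  write_point_cloud(gp$ground, file.path(out_dir, "map_ground.pcd"))
  write_point_cloud(gp$nonground, file.path(out_dir, "map_nonground.pcd"))
  write_manifest(cfg, out_dir, "map", list(n_map_points = nrow(mp)))
  list(odometry = file.path(out_dir, "odometry.csv"),
       map = file.path(out_dir, "map.pcd"))
}

segmentation_input <- function(cfg, out_dir) {
  if (cfg$segmentation$input == "map" &&
      file.exists(file.path(out_dir, "map_nonground.pcd"))) {
    cloud <- read_point_cloud(file.path(out_dir, "map_nonground.pcd"))
    cloud$label <- cloud$label %||% rep(NA_integer_, nrow(cloud))
    cloud
  } else {
    cloud <- read_point_cloud(file.path(out_dir, "map_points.pcd"))
    remove_ground_by_sensor_height(cloud, cfg$sensor$mount_height)$nonground
  }
}

run_segmentation_stage <- function(cfg, cloud, m = NULL) {
  sg <- cfg$segmentation
  segment_trees(cloud, radius = sg$radius, min_size = sg$min_size, k = sg$k,
                m = m %||% sg$m, in_row_spacing = cfg$scene$in_row_spacing,
                second_radius = sg$second_radius,
                second_min_size = sg$second_min_size)
}

stage_segment <- function(cfg, out_dir) {
  cloud <- segmentation_input(cfg, out_dir)
  inst <- run_segmentation_stage(cfg, cloud)
  tree_dir <- file.path(out_dir, "trees")
  dir.create(tree_dir, showWarnings = FALSE)
  man <- lapply(inst, function(x) {
    df <- cloud[x$points, c("x", "y", "z", if ("label" %in% names(cloud)) "label")]
    write_point_cloud(df, file.path(tree_dir, sprintf("tree_%03d.pcd", x$id)))
    tally <- table(factor(x$provenance,
                          levels = c("first-pass", "second-pass", "knn-recovered")))
    data.frame(id = x$id, n_points = length(x$points),
               n_first_pass = tally[["first-pass"]],
               n_second_pass = tally[["second-pass"]],
               n_knn_recovered = tally[["knn-recovered"]])
  })
  utils::write.csv(do.call(rbind, man), file.path(out_dir, "trees_manifest.csv"),
                   row.names = FALSE)
  write_manifest(cfg, out_dir, "segment", list(n_instances = length(inst)))
  list(trees = tree_dir, manifest = file.path(out_dir, "trees_manifest.csv"))
}

read_instances <- function(out_dir) {
  man <- utils::read.csv(file.path(out_dir, "trees_manifest.csv"))
  lapply(man$id, function(i)
    read_point_cloud(file.path(out_dir, "trees", sprintf("tree_%03d.pcd", i))))
}

stage_measure <- function(cfg, out_dir) {
  full <- read_point_cloud(file.path(out_dir, "map_points.pcd"))
  ground <- remove_ground_by_sensor_height(full, cfg$sensor$mount_height)$ground
  plane <- fit_ground_plane_ransac(ground, inlier_threshold = cfg$metrics$ransac_threshold,
                                   max_iter = cfg$metrics$ransac_iter,
                                   seed = cfg$seed + 5)
  trees <- read_instances(out_dir)
  rows <- lapply(seq_along(trees), function(i) {
    p <- trees[[i]]
    av <- tryCatch(alpha_shape_volume(p, cfg$metrics$alpha),
                   error = function(e) list(volume = NA_real_, n_tet = NA_integer_))
    data.frame(id = i, n_points = nrow(p), height_m = crown_height(p, plane),
               volume_m3 = av$volume, n_tet = av$n_tet, alpha = cfg$metrics$alpha)
  })
  metrics <- do.call(rbind, rows)
  utils::write.csv(metrics, file.path(out_dir, "canopy_metrics.csv"), row.names = FALSE)
  yaml::write_yaml(list(plane = as.numeric(plane$coef), inliers = length(plane$inliers),
                        threshold = plane$threshold, seed = plane$seed),
                   file.path(out_dir, "ground_plane.yaml"))
  write_manifest(cfg, out_dir, "measure", list(n_trees = nrow(metrics)))
  list(metrics = file.path(out_dir, "canopy_metrics.csv"))
}

truth_metrics <- function(trees_csv) {
  tr <- utils::read.csv(trees_csv)
  tr$height_truth <- tr$base_height + tr$y
  tr$volume_truth <- ifelse(tr$shape == "cone",
                            reference_volume("cone", tr$x, tr$y),
                            reference_volume("ellipsoid", tr$x, tr$y))
  tr
}

stage_evaluate <- function(cfg, out_dir) {
  cloud <- segmentation_input(cfg, out_dir)
  inst <- run_segmentation_stage(cfg, cloud)
  ev <- evaluate_segmentation(inst, cloud$label)
  res <- list(successes = ev$successes, failures = ev$failures,
              success_rate = ev$rate)
  # metric agreement vs scene truth where instances map cleanly to trees
  tr <- truth_metrics(file.path(out_dir, "scene_trees.csv"))
  met_path <- file.path(out_dir, "canopy_metrics.csv")
  if (file.exists(met_path)) {
    met <- utils::read.csv(met_path)
    trees <- read_instances(out_dir)
    lab <- vapply(trees, function(p) {
      tl <- p$label[p$label > 0]
      if (!length(tl)) NA_integer_ else as.integer(names(which.max(table(tl))))
    }, integer(1))
    ok <- !is.na(lab) & !duplicated(lab) & !is.na(met$volume_m3)
    if (sum(ok) >= 3) {
      hm <- r2_rmse(tr$height_truth[lab[ok]], met$height_m[ok])
      vm <- r2_rmse(tr$volume_truth[lab[ok]], met$volume_m3[ok])
      res <- c(res, list(height_r2 = hm$r2, height_rmse_m = hm$rmse,
                         volume_r2 = vm$r2, volume_rmse_m3 = vm$rmse,
                         n_matched_trees = sum(ok)))
    }
  }
  utils::write.csv(as.data.frame(res), file.path(out_dir, "evaluation.csv"),
                   row.names = FALSE)
  write_manifest(cfg, out_dir, "evaluate", res)
  list(evaluation = file.path(out_dir, "evaluation.csv"))
}

stage_sweep <- function(cfg, out_dir) {
  cloud <- segmentation_input(cfg, out_dir)
  rows <- lapply(cfg$sweep$m_values, function(mv) {
    inst <- run_segmentation_stage(cfg, cloud, m = mv)
    ev <- evaluate_segmentation(inst, cloud$label)
    data.frame(m = mv, successes = ev$successes, failures = ev$failures,
               success_rate = ev$rate)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out_dir, "sor_sweep.csv"), row.names = FALSE)
  write_manifest(cfg, out_dir, "sweep", list(n_settings = nrow(tab)))
  list(sor_sweep = file.path(out_dir, "sor_sweep.csv"))
}
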