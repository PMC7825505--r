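#' Pipeline configuration
#'
#' A nested list with one block per stage; [default_config()] carries the
#' system's operating points (16 x 1800 range image, 2/20/4/40 feature
#' budget, 20 mm clustering radius, SOR k = 50 / m = 0.01, alpha = 0.25 m,
#' 20 cm ground offset above the sensor mount height). [load_config()]
#' reads a YAML file and merges it over the defaults;
#' [validate_config()] checks every field against its stage's
#' preconditions before anything runs.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 42,
    scene = list(n_rows = 2, trees_per_row = 6, overlap_fraction = 0.2,
                 row_spacing = 5, in_row_spacing = 4,
                 density = 6000, ground_density = 250, noise_sigma = 0.003,
                 interior_fraction = 0.15, bridge_points = 900),
    sensor = list(mount_height = 0.8,
                  lidar = list(n_beams = 16, vertical_fov = 15,
                               azimuth_steps = 1800, range_sigma = 0.02,
                               max_range = 150, sweep_rate = 10),
                  imu = list(rate = 400, gyro_noise = 0.003, accel_noise = 0.012)),
    simulate = list(speed = 1.0, n_sweeps = 20, static_time = 1,
                    pitch_amp = 0.5, roll_amp = 0.3),
    preprocess = list(ground_angle = 10, cluster_angle = 20,
                      min_cluster_size = 30, half_window = 5,
                      edge_threshold = 0.1, plane_threshold = 0.1),
    odometry = list(meas_sigma = 0.1, corr_radius = 0.5, max_iter = 10,
                    tol = 1e-6, init_window = 1),
    mapping = list(eps_x = 0.1, eps_y = 0.1, voxel_size = 0.05,
                   rotation_constraint = TRUE),
    segmentation = list(radius = 0.02, min_size = 50, k = 50, m = 0.01,
                        second_radius = 0.25, second_min_size = 30,
                        input = "sampled"),
    metrics = list(alpha = 0.25, ransac_threshold = 0.05, ransac_iter = 500,
                   max_points_per_tree = 20000),
    sweep = list(m_values = c(0.2, 0.1, 0.08, 0.04, 0.01, 0.008, 0.006, 0.004))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' @rdname default_config
#' @param path YAML configuration file.
#' @export
load_config <- function(path) {
  cfg <- merge_config(default_config(), yaml::read_yaml(path))
  validate_config(cfg)
}

config_error <- function(field, msg) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = paste0("invalid config field '", field, "': ", msg),
                      call = NULL, field = field)))
}

#' @rdname default_config
#' @param cfg configuration list.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, field, msg) if (!isTRUE(ok)) config_error(field, msg)
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed", "must be an integer")
  sc <- cfg$scene
  chk(sc$n_rows >= 1 && sc$trees_per_row >= 1, "scene", "tree counts must be positive")
  chk(sc$overlap_fraction >= 0 && sc$overlap_fraction <= 1,
      "scene.overlap_fraction", "must lie in [0, 1]")
  chk(sc$density > 0, "scene.density", "must be positive")
  chk(sc$noise_sigma >= 0, "scene.noise_sigma", "must be non-negative")
  chk(cfg$sensor$mount_height > 0, "sensor.mount_height", "must be positive")
  chk(cfg$sensor$lidar$range_sigma >= 0, "sensor.lidar.range_sigma", "must be non-negative")
  chk(cfg$sensor$imu$rate > cfg$sensor$lidar$sweep_rate,
      "sensor.imu.rate", "must exceed the LiDAR sweep rate")
  chk(cfg$simulate$speed > 0, "simulate.speed", "must be positive")
  chk(cfg$preprocess$half_window >= 1, "preprocess.half_window", "must be >= 1")
  chk(cfg$odometry$meas_sigma > 0, "odometry.meas_sigma", "must be positive")
  mp <- cfg$mapping
  chk(mp$eps_x > 0 && mp$eps_x <= 1 && mp$eps_y > 0 && mp$eps_y <= 1,
      "mapping.eps", "information ratios must lie in (0, 1]")
  chk(mp$voxel_size > 0, "mapping.voxel_size", "must be positive")
  sg <- cfg$segmentation
  chk(sg$radius > 0, "segmentation.radius", "must be positive")
  chk(sg$k >= 1, "segmentation.k", "must be >= 1")
  chk(sg$m > 0, "segmentation.m", "must be positive")
  chk(sg$input %in% c("sampled", "map"), "segmentation.input",
      "must be 'sampled' or 'map'")
  chk(cfg$metrics$alpha > 0, "metrics.alpha", "must be positive")
  chk(cfg$metrics$ransac_threshold > 0, "metrics.ransac_threshold", "must be positive")
  invisible(cfg)
}
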