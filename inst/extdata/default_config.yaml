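# Default pipeline configuration (mirrors default_config()); values are the
# system's reference operating points, otherwise the package defaults
# documented in the methods vignette.
seed: 42
scene:
  n_rows: 2
  trees_per_row: 6
  overlap_fraction: 0.2
  row_spacing: 5        # m between rows
  in_row_spacing: 4     # m within a row
  density: 6000         # crown points per m^2 of surface (map-scale)
  ground_density: 250   # ground points per m^2
  noise_sigma: 0.003    # m, effective map noise after multi-view averaging
  interior_fraction: 0.15
  bridge_points: 900
sensor:
  mount_height: 0.8     # m, LiDAR centre above ground
  lidar:
    n_beams: 16
    vertical_fov: 15    # degrees, half-angle
    azimuth_steps: 1800
    range_sigma: 0.02   # m
    max_range: 150      # m
    sweep_rate: 10      # Hz
  imu:
    rate: 400           # Hz
    gyro_noise: 0.003   # rad/s per sample
    accel_noise: 0.012  # m/s^2 per sample
simulate:
  speed: 1.0            # m/s
  n_sweeps: 20
  static_time: 1        # s stationary dwell for initialization
  pitch_amp: 0.5        # degrees
  roll_amp: 0.3         # degrees
preprocess:
  ground_angle: 10      # degrees
  cluster_angle: 20     # degrees
  min_cluster_size: 30
  half_window: 5
  edge_threshold: 0.1
  plane_threshold: 0.1
odometry:
  meas_sigma: 0.1       # m, residual error budget
  corr_radius: 0.5      # m
  max_iter: 10
  tol: 1.0e-6
  init_window: 1        # s
mapping:
  eps_x: 0.1
  eps_y: 0.1
  voxel_size: 0.05      # m
  rotation_constraint: true
segmentation:
  radius: 0.02          # m, Euclidean clustering threshold
  min_size: 50
  k: 50                 # SOR neighbour count
  m: 0.01               # SOR standard-deviation multiplier
  second_radius: 0.25   # m, re-clustering radius for the SOR core
  second_min_size: 30
  input: sampled
metrics:
  alpha: 0.25           # m, alpha-shape roller radius
  ransac_threshold: 0.05
  ransac_iter: 500
  max_points_per_tree: 20000
sweep:
  m_values: [0.2, 0.1, 0.08, 0.04, 0.01, 0.008, 0.006, 0.004]
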