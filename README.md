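# orchardcanopy

Mobile LiDAR–inertial mapping and canopy phenotyping for orchards, rebuilt
at desk scale on fully synthetic data.

Orchard managers need per-tree crown height and crown volume — they drive
spraying, pruning and yield decisions — but GNSS-based mobile scanning
fails under dense canopies. The alternative is a self-contained
LiDAR-inertial pipeline: a tracked robot with a 16-beam spinning LiDAR
(10 Hz, ±2 cm) and a 400 Hz IMU drives the inter-row corridors; an
iterated **error-state Kalman filter** estimates the trajectory by fusing
IMU propagation of the state `x = (p, v, q, b_a, b_g, g)` (error state
`δx = [δp, δv, δθ, δb_a, δb_g, δg]`, covariance `P`) with point-to-line /
point-to-plane residuals on LOAM-style edge and planar features; sweeps
are registered into a global map with a **rotation constraint**
`J_θ^z = J_θ R̂ᵀ Ω_z`, `Ω_z = diag(ε_x, ε_y, 1)`, that attenuates the
LiDAR's roll/pitch information so the map stays gravity-aligned and the
notorious z-drift is suppressed; ground is stripped by the sensor-height
rule `z < −d + 0.20 m`; trees are separated by **two-step segmentation**
(Euclidean clustering at r = 20 mm; joined canopies split by statistical
outlier removal with k = 50 neighbours and multiplier m = 0.01, then
k-nearest-neighbour recovery of the filtered points); and each tree is
measured by RANSAC ground-plane distance (crown height) and the
**alpha-shape volume** — 3D Delaunay tetrahedra with circumsphere radius
≤ α = 0.25 m, `V = Σ ⅓·A·h` — validated against the tape-measure solids
`V = πx²y/12` (cone) and `πx²y/6` (ellipsoid).

No field recordings are used: the package ships a ground-truthed synthetic
orchard generator (row lattice 5 m × 4 m, ellipsoidal/conical crowns,
analytic ray-cast sweeps with per-column sensor poses, analytic IMU
streams), so every stage is tested against known truth.

## Worked example

```r
library(orchardcanopy)

# a 50-tree orchard, 2 cm range noise
scene <- generate_scene(5, 10, overlap_fraction = 0, seed = 21)
cloud <- sample_scene_points(scene, density = 800, sigma = 0.02, seed = 22,
                             ground_density = 80, interior_fraction = 0.35)

plane <- fit_ground_plane_ransac(cloud[cloud$label == 0, ], seed = 23)
round(plane$coef, 4)
#> [1] 0.0000 0.0000 1.0000 0.8005

tree1 <- cloud[cloud$label == 1, ]
crown_height(tree1, plane)             # metres above the fitted ground
alpha_shape_volume(tree1, 0.25)$volume # m^3 at the 0.25 m roller radius
```

Across all 50 trees of that scene the suite measures height RMSE 0.0375 m
with R² 0.994 against truth, and alpha-shape volume R² 0.98 against the
analytic crown solids — the volumes run ~7 % high, the expected inflation
of a 0.25 m roller over a noisy surface.

The full pipeline, file-based and resumable:

```sh
exec/canopy all --config cfg.yaml --out out/ --seed 42
exec/canopy sweep --out out/        # Table-style SOR multiplier sweep
```

or from R via `run_pipeline("all", default_config(), out_dir = "out")`.

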