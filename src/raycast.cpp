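// Analytic ray casting for the synthetic-orchard LiDAR: per-column sensor
// pose (supports intra-sweep motion), 16 beams, first intersection with the
// ground plane or a crown surface (ellipsoid / cone lateral surface).
// Range noise uses R's RNG so set.seed() on the R side controls it.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Hit { double t; int label; };

inline bool betterHit(double t, int label, double tmin, double tmax, Hit& best) {
  if (t < tmin || t > tmax) return false;
  if (t < best.t) { best.t = t; best.label = label; return true; }
  return false;
}

} // namespace

// [[Rcpp::export]]
List cpp_raycast(NumericMatrix origin,      // n_az x 3 sensor position per column (world)
                 NumericMatrix quat,        // n_az x 4 body->world rotation (w,x,y,z)
                 NumericVector elev_deg,    // per-ring elevation angles
                 NumericVector ground,      // plane a,b,c,d with ax+by+cz+d = 0
                 bool use_ground,
                 NumericMatrix trees,       // cols: shape(0 ellipsoid,1 cone), cx, cy, base_z, diam, height
                 double sigma, double min_range, double max_range) {
  int n_az = origin.nrow();
  int n_rings = elev_deg.size();
  int n_tree = trees.nrow();
  const double deg = M_PI / 180.0;
  std::vector<int> colv, ringv, labelv;
  std::vector<double> xv, yv, zv, rangev;
  colv.reserve(n_az * n_rings / 2);
  RNGScope scope;
  for (int c = 0; c < n_az; ++c) {
    // cast at the bin centre so projection back to columns is unambiguous
    double az = (360.0 * (c + 0.5) / n_az) * deg;
    double ca = std::cos(az), sa = std::sin(az);
    double qw = quat(c, 0), qx = quat(c, 1), qy = quat(c, 2), qz = quat(c, 3);
    // rotation matrix from quaternion
    double R00 = 1 - 2 * (qy * qy + qz * qz), R01 = 2 * (qx * qy - qw * qz), R02 = 2 * (qx * qz + qw * qy);
    double R10 = 2 * (qx * qy + qw * qz), R11 = 1 - 2 * (qx * qx + qz * qz), R12 = 2 * (qy * qz - qw * qx);
    double R20 = 2 * (qx * qz - qw * qy), R21 = 2 * (qy * qz + qw * qx), R22 = 1 - 2 * (qx * qx + qy * qy);
    double ox = origin(c, 0), oy = origin(c, 1), oz = origin(c, 2);
    for (int r = 0; r < n_rings; ++r) {
      double el = elev_deg[r] * deg;
      double ce = std::cos(el), se = std::sin(el);
      // direction in sensor frame, then world
      double bx = ce * ca, by = ce * sa, bz = se;
      double dx = R00 * bx + R01 * by + R02 * bz;
      double dy = R10 * bx + R11 * by + R12 * bz;
      double dz = R20 * bx + R21 * by + R22 * bz;
      Hit best; best.t = max_range + 1.0; best.label = -1;
      if (use_ground) {
        double den = ground[0] * dx + ground[1] * dy + ground[2] * dz;
        if (std::fabs(den) > 1e-12) {
          double t = -(ground[0] * ox + ground[1] * oy + ground[2] * oz + ground[3]) / den;
          betterHit(t, 0, min_range, max_range, best);
        }
      }
      for (int k = 0; k < n_tree; ++k) {
        double shape = trees(k, 0);
        double cx = trees(k, 1), cy = trees(k, 2), basez = trees(k, 3);
        double diam = trees(k, 4), h = trees(k, 5);
        if (shape < 0.5) {
          // ellipsoid: centre (cx, cy, basez + h/2), semi-axes (diam/2, diam/2, h/2)
          double a = diam / 2, cc = h / 2;
          double zc = basez + h / 2;
          double px = (ox - cx) / a, py = (oy - cy) / a, pz = (oz - zc) / cc;
          double wx = dx / a, wy = dy / a, wz = dz / cc;
          double A = wx * wx + wy * wy + wz * wz;
          double B = 2 * (px * wx + py * wy + pz * wz);
          double C = px * px + py * py + pz * pz - 1.0;
          double disc = B * B - 4 * A * C;
          if (disc >= 0 && A > 0) {
            double sq = std::sqrt(disc);
            double t1 = (-B - sq) / (2 * A), t2 = (-B + sq) / (2 * A);
            betterHit(t1, k + 1, min_range, max_range, best);
            betterHit(t2, k + 1, min_range, max_range, best);
          }
        } else {
          // cone: apex (cx, cy, basez + h), opening downward to base radius diam/2
          double za = basez + h;
          double kk = (diam / 2) / h;
          double k2 = kk * kk;
          double px = ox - cx, py = oy - cy;
          double m = za - oz;
          double A = dx * dx + dy * dy - k2 * dz * dz;
          double B = 2 * (px * dx + py * dy + k2 * m * dz);
          double C = px * px + py * py - k2 * m * m;
          double disc = B * B - 4 * A * C;
          if (disc >= 0 && std::fabs(A) > 1e-14) {
            double sq = std::sqrt(disc);
            for (int s = -1; s <= 1; s += 2) {
              double t = (-B + s * sq) / (2 * A);
              double z = oz + t * dz;
              if (z >= basez && z <= za) betterHit(t, k + 1, min_range, max_range, best);
            }
          }
        }
      }
      if (best.label >= 0) {
        double t = best.t + (sigma > 0 ? norm_rand() * sigma : 0.0);
        colv.push_back(c);
        ringv.push_back(r);
        xv.push_back(t * bx);
        yv.push_back(t * by);
        zv.push_back(t * bz);
        rangev.push_back(t);
        labelv.push_back(best.label);
      }
    }
  }
  return List::create(_["col"] = wrap(colv), _["ring"] = wrap(ringv),
                      _["x"] = wrap(xv), _["y"] = wrap(yv), _["z"] = wrap(zv),
                      _["range"] = wrap(rangev), _["label"] = wrap(labelv));
}
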