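// Monte-Carlo streamline propagation over a voxelwise fiber-orientation
// field. Positions are continuous 1-based voxel coordinates (voxel centers at
// integers). Orientations are axial (v and -v equivalent); the sampler
// resolves sign against the previous step direction. Masks are looked up at
// the nearest voxel; orientation populations are interpolated trilinearly.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Field {
  const double *dirs;     // nx*ny*nz*3*P
  const double *weights;  // nx*ny*nz*P
  const double *kappa;    // nx*ny*nz
  int nx, ny, nz, P;
  long nvox;

  long vox(int x, int y, int z) const {
    return x + (long)nx * (y + (long)ny * z);
  }
};

inline int nearest(double p) { return (int)std::lround(p) - 1; }

inline bool in_grid(const Field &f, int x, int y, int z) {
  return x >= 0 && y >= 0 && z >= 0 && x < f.nx && y < f.ny && z < f.nz;
}

// Sample a unit vector from a von-Mises-Fisher distribution on S2 around mu.
inline void vmf_sample(const double mu[3], double kappa, double out[3]) {
  if (!R_finite(kappa) || kappa > 1e8) {
    out[0] = mu[0]; out[1] = mu[1]; out[2] = mu[2];
    return;
  }
  double u = unif_rand();
  double w;
  if (kappa < 1e-8) {
    w = 2.0 * u - 1.0;  // uniform on the sphere
  } else {
    double e2k = std::exp(-2.0 * kappa);
    w = 1.0 + std::log(u + (1.0 - u) * e2k) / kappa;
    if (w < -1.0) w = -1.0;
    if (w > 1.0) w = 1.0;
  }
  // orthonormal basis perpendicular to mu
  double a[3];
  if (std::fabs(mu[0]) < 0.9) { a[0] = 1; a[1] = 0; a[2] = 0; }
  else { a[0] = 0; a[1] = 1; a[2] = 0; }
  double e1[3] = {mu[1] * a[2] - mu[2] * a[1],
                  mu[2] * a[0] - mu[0] * a[2],
                  mu[0] * a[1] - mu[1] * a[0]};
  double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  e1[0] /= n1; e1[1] /= n1; e1[2] /= n1;
  double e2[3] = {mu[1] * e1[2] - mu[2] * e1[1],
                  mu[2] * e1[0] - mu[0] * e1[2],
                  mu[0] * e1[1] - mu[1] * e1[0]};
  double t = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - w * w));
  for (int i = 0; i < 3; ++i)
    out[i] = w * mu[i] + s * (std::cos(t) * e1[i] + std::sin(t) * e2[i]);
}

// Draw an orientation at continuous position p. prev is the previous step
// direction or NULL (then the axial sign is random). Returns false on
// termination (outside grid / zero orientation support).
bool sample_orientation_at(const Field &f, const double p[3],
                           const double *prev, double out[3]) {
  int vx = nearest(p[0]), vy = nearest(p[1]), vz = nearest(p[2]);
  if (!in_grid(f, vx, vy, vz)) return false;
  long v = f.vox(vx, vy, vz);

  // population choice at the nearest voxel, proportional to weights
  int pop = 0;
  double wtot = 0.0;
  for (int j = 0; j < f.P; ++j) wtot += f.weights[v + f.nvox * j];
  if (wtot < 1e-12) return false;
  if (f.P > 1) {
    double u = unif_rand() * wtot, acc = 0.0;
    for (int j = 0; j < f.P; ++j) {
      acc += f.weights[v + f.nvox * j];
      if (u <= acc) { pop = j; break; }
    }
  }

  // sign reference: previous direction, else the nearest voxel's mean
  double ref[3];
  if (prev) {
    ref[0] = prev[0]; ref[1] = prev[1]; ref[2] = prev[2];
  } else {
    for (int i = 0; i < 3; ++i)
      ref[i] = f.dirs[v + f.nvox * (i + 3L * pop)];
  }

  // trilinear interpolation of the chosen population's axial directions
  int bx = (int)std::floor(p[0] - 1.0), by = (int)std::floor(p[1] - 1.0),
      bz = (int)std::floor(p[2] - 1.0);
  double fx = (p[0] - 1.0) - bx, fy = (p[1] - 1.0) - by, fz = (p[2] - 1.0) - bz;
  double m[3] = {0, 0, 0};
  double ksum = 0, kw = 0;
  for (int cz = 0; cz <= 1; ++cz)
    for (int cy = 0; cy <= 1; ++cy)
      for (int cx = 0; cx <= 1; ++cx) {
        int x = bx + cx, y = by + cy, z = bz + cz;
        if (!in_grid(f, x, y, z)) continue;
        double tw = (cx ? fx : 1 - fx) * (cy ? fy : 1 - fy) * (cz ? fz : 1 - fz);
        if (tw <= 0) continue;
        long c = f.vox(x, y, z);
        double wgt = f.weights[c + f.nvox * pop];
        if (wgt <= 0) continue;
        double d[3];
        for (int i = 0; i < 3; ++i) d[i] = f.dirs[c + f.nvox * (i + 3L * pop)];
        double dp = d[0] * ref[0] + d[1] * ref[1] + d[2] * ref[2];
        double sgn = (dp < 0) ? -1.0 : 1.0;
        for (int i = 0; i < 3; ++i) m[i] += tw * wgt * sgn * d[i];
        ksum += tw * wgt * f.kappa[c];
        kw += tw * wgt;
      }
  double mn = std::sqrt(m[0] * m[0] + m[1] * m[1] + m[2] * m[2]);
  if (mn < 1e-8) return false;
  for (int i = 0; i < 3; ++i) m[i] /= mn;
  double kap = (kw > 0) ? ksum / kw : 0.0;
  if (!R_finite(f.kappa[v])) kap = f.kappa[v];  // Inf survives averaging intent

  vmf_sample(m, kap, out);

  if (prev) {
    double dp = out[0] * prev[0] + out[1] * prev[1] + out[2] * prev[2];
    if (dp < 0) { out[0] = -out[0]; out[1] = -out[1]; out[2] = -out[2]; }
  } else if (unif_rand() < 0.5) {
    out[0] = -out[0]; out[1] = -out[1]; out[2] = -out[2];
  }
  return true;
}

// One directed half-path. Visits are recorded through the callback.
template <typename Visit>
void propagate_half(const Field &f, const int *brain, const int *stop_mask,
                    double p0[3], double d0[3], double step, int max_steps,
                    double cos_lim, Visit visit) {
  double p[3] = {p0[0], p0[1], p0[2]};
  double d[3] = {d0[0], d0[1], d0[2]};
  for (int s = 0; s < max_steps; ++s) {
    double pn[3] = {p[0] + step * d[0], p[1] + step * d[1], p[2] + step * d[2]};
    int vx = nearest(pn[0]), vy = nearest(pn[1]), vz = nearest(pn[2]);
    if (!in_grid(f, vx, vy, vz)) break;
    long v = f.vox(vx, vy, vz);
    if (!brain[v]) break;
    if (stop_mask[v]) break;
    visit(v, pn);
    double dn[3];
    if (!sample_orientation_at(f, pn, d, dn)) break;
    double dp = dn[0] * d[0] + dn[1] * d[1] + dn[2] * d[2];
    if (dp < cos_lim - 1e-9) break;
    d[0] = dn[0]; d[1] = dn[1]; d[2] = dn[2];
    p[0] = pn[0]; p[1] = pn[1]; p[2] = pn[2];
  }
}

Field make_field(NumericVector dirs, NumericVector weights, NumericVector kappa) {
  IntegerVector dd = dirs.attr("dim");
  Field f;
  f.nx = dd[0]; f.ny = dd[1]; f.nz = dd[2];
  f.P = (dd.size() == 5) ? dd[4] : 1;
  f.nvox = (long)f.nx * f.ny * f.nz;
  f.dirs = dirs.begin();
  f.weights = weights.begin();
  f.kappa = kappa.begin();
  return f;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_sample_orientations(NumericVector dirs, NumericVector weights,
                                      NumericVector kappa, NumericVector pos,
                                      Nullable<NumericVector> prev, int n) {
  Field f = make_field(dirs, weights, kappa);
  double p[3] = {pos[0], pos[1], pos[2]};
  double pv[3];
  const double *pp = nullptr;
  if (prev.isNotNull()) {
    NumericVector q(prev);
    pv[0] = q[0]; pv[1] = q[1]; pv[2] = q[2];
    pp = pv;
  }
  NumericMatrix out(n, 3);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double d[3];
    if (!sample_orientation_at(f, p, pp, d))
      stop("position outside the orientation support");
    out(i, 0) = d[0]; out(i, 1) = d[1]; out(i, 2) = d[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_propagate(NumericVector dirs, NumericVector weights,
                            NumericVector kappa, IntegerVector brain,
                            IntegerVector stop_mask, NumericVector start,
                            Nullable<NumericVector> init_dir, double step,
                            int max_steps, double cos_lim) {
  Field f = make_field(dirs, weights, kappa);
  RNGScope scope;
  double p0[3] = {start[0], start[1], start[2]};
  double d0[3];
  if (init_dir.isNotNull()) {
    NumericVector q(init_dir);
    double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2]);
    d0[0] = q[0] / n; d0[1] = q[1] / n; d0[2] = q[2] / n;
  } else {
    if (!sample_orientation_at(f, p0, nullptr, d0))
      stop("start position outside the orientation support");
  }
  std::vector<double> path;
  path.insert(path.end(), p0, p0 + 3);
  propagate_half(f, brain.begin(), stop_mask.begin(), p0, d0, step, max_steps,
                 cos_lim, [&](long, const double *pn) {
                   path.insert(path.end(), pn, pn + 3);
                 });
  int np = (int)(path.size() / 3);
  NumericMatrix out(np, 3);
  for (int i = 0; i < np; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = path[3 * i + j];
  return out;
}

// [[Rcpp::export]]
List cpp_track(NumericVector dirs, NumericVector weights, NumericVector kappa,
               IntegerVector brain, IntegerVector stop_mask,
               IntegerVector targets, int n_targets, IntegerMatrix seeds,
               int n_samples, double step, int max_steps, double cos_lim) {
  Field f = make_field(dirs, weights, kappa);
  int n_seed = seeds.nrow();
  RNGScope scope;

  std::vector<int> stamp(f.nvox, -1);
  std::vector<int> row_count(f.nvox, 0);
  std::vector<long> touched;
  touched.reserve(4096);
  std::vector<int> tstamp(n_targets, -1);
  IntegerMatrix target_counts(n_seed, n_targets);

  std::vector<int> tri_i, tri_j, tri_x;

  for (int si = 0; si < n_seed; ++si) {
    std::fill(stamp.begin(), stamp.end(), -1);
    touched.clear();
    double p0[3] = {(double)seeds(si, 0), (double)seeds(si, 1),
                    (double)seeds(si, 2)};
    int v0x = nearest(p0[0]), v0y = nearest(p0[1]), v0z = nearest(p0[2]);
    bool start_ok = in_grid(f, v0x, v0y, v0z);
    long v0 = start_ok ? f.vox(v0x, v0y, v0z) : -1;

    for (int s = 0; s < n_samples; ++s) {
      std::fill(tstamp.begin(), tstamp.end(), -1);
      auto visit = [&](long v, const double *) {
        if (stamp[v] != s) {
          stamp[v] = s;
          if (row_count[v] == 0) touched.push_back(v);
          row_count[v] += 1;
        }
        int t = targets[v];
        if (t > 0 && tstamp[t - 1] != s) {
          tstamp[t - 1] = s;
          target_counts(si, t - 1) += 1;
        }
      };
      if (start_ok && brain[v0]) visit(v0, p0);
      double d0[3];
      if (!sample_orientation_at(f, p0, nullptr, d0)) continue;
      propagate_half(f, brain.begin(), stop_mask.begin(), p0, d0, step,
                     max_steps, cos_lim, visit);
      double dneg[3] = {-d0[0], -d0[1], -d0[2]};
      propagate_half(f, brain.begin(), stop_mask.begin(), p0, dneg, step,
                     max_steps, cos_lim, visit);
    }
    for (long v : touched) {
      tri_i.push_back(si + 1);
      tri_j.push_back((int)v + 1);
      tri_x.push_back(row_count[v]);
      row_count[v] = 0;
    }
  }
  return List::create(_["i"] = wrap(tri_i), _["j"] = wrap(tri_j),
                      _["x"] = wrap(tri_x),
                      _["target_counts"] = target_counts);
}
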