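#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Moller-Trumbore ray/triangle intersection over all faces for a batch of
// directions from a common origin.  For each direction returns the FARTHEST
// hit parameter t (> 1e-9), or -1 when the ray misses, plus the number of
// distinct surface crossings (hits deduplicated by t so that a ray passing
// exactly through a shared vertex or edge counts one crossing, keeping the
// parity test on watertight meshes meaningful).
// [[Rcpp::export]]
List cpp_raycast(NumericMatrix vertices, IntegerMatrix faces0,
                 NumericVector origin, NumericMatrix directions) {
  const int nf = faces0.nrow();
  const int nd = directions.nrow();
  const double t_min = 1e-9;
  const double det_eps = 1e-12;

  std::vector<double> v0x(nf), v0y(nf), v0z(nf),
      e1x(nf), e1y(nf), e1z(nf), e2x(nf), e2y(nf), e2z(nf);
  std::vector<bool> degen(nf, false);
  for (int i = 0; i < nf; ++i) {
    const int a = faces0(i, 0), b = faces0(i, 1), c = faces0(i, 2);
    v0x[i] = vertices(a, 0); v0y[i] = vertices(a, 1); v0z[i] = vertices(a, 2);
    e1x[i] = vertices(b, 0) - v0x[i];
    e1y[i] = vertices(b, 1) - v0y[i];
    e1z[i] = vertices(b, 2) - v0z[i];
    e2x[i] = vertices(c, 0) - v0x[i];
    e2y[i] = vertices(c, 1) - v0y[i];
    e2z[i] = vertices(c, 2) - v0z[i];
    // zero-area triangles are skipped, not fatal
    const double nx = e1y[i] * e2z[i] - e1z[i] * e2y[i];
    const double ny = e1z[i] * e2x[i] - e1x[i] * e2z[i];
    const double nz = e1x[i] * e2y[i] - e1y[i] * e2x[i];
    if (nx * nx + ny * ny + nz * nz < 1e-30) degen[i] = true;
  }
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  NumericVector t_far(nd);
  IntegerVector nhits(nd);
  std::vector<double> ts;
  for (int d = 0; d < nd; ++d) {
    const double dx = directions(d, 0), dy = directions(d, 1), dz = directions(d, 2);
    ts.clear();
    double best = -1.0;
    for (int i = 0; i < nf; ++i) {
      if (degen[i]) continue;
      // p = dir x e2
      const double px = dy * e2z[i] - dz * e2y[i];
      const double py = dz * e2x[i] - dx * e2z[i];
      const double pz = dx * e2y[i] - dy * e2x[i];
      const double det = e1x[i] * px + e1y[i] * py + e1z[i] * pz;
      if (std::fabs(det) < det_eps) continue;
      const double inv = 1.0 / det;
      const double tx = ox - v0x[i], ty = oy - v0y[i], tz = oz - v0z[i];
      const double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      // q = tvec x e1
      const double qx = ty * e1z[i] - tz * e1y[i];
      const double qy = tz * e1x[i] - tx * e1z[i];
      const double qz = tx * e1y[i] - ty * e1x[i];
      const double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      const double t = (e2x[i] * qx + e2y[i] * qy + e2z[i] * qz) * inv;
      if (t <= t_min) continue;
      ts.push_back(t);
      if (t > best) best = t;
    }
    t_far[d] = best;
    if (ts.empty()) {
      nhits[d] = 0;
    } else {
      std::sort(ts.begin(), ts.end());
      int k = 1;
      for (size_t j = 1; j < ts.size(); ++j) {
        if (ts[j] - ts[j - 1] > 1e-9 * (1.0 + ts[j])) ++k;
      }
      nhits[d] = k;
    }
  }
  return List::create(_["t"] = t_far, _["hits"] = nhits);
}
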