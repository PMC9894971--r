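#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact radiological path length (Siddon traversal) of a set of rays through
// a regular voxel grid. The grid holds attenuation coefficients (mm^-1),
// occupies [0, nx*vs] x [0, ny*vs] x [0, nz*vs] (mm) and is indexed
// column-major as vol[i + nx*(j + ny*k)]. Rays are given by an origin and a
// unit direction per column; the returned value is the line integral of the
// attenuation along each ray (unitless attenuance). Exact for
// piecewise-constant volumes: every voxel crossed contributes mu * chord.
// [[Rcpp::export]]
NumericVector siddon_raycast(NumericVector vol, IntegerVector dims, double vs,
                             NumericMatrix origin, NumericMatrix dir) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nray = origin.ncol();
  const double bx = nx * vs, by = ny * vs, bz = nz * vs;
  const double inf = std::numeric_limits<double>::infinity();
  NumericVector out(nray);

  for (int r = 0; r < nray; ++r) {
    const double ox = origin(0, r), oy = origin(1, r), oz = origin(2, r);
    const double dx = dir(0, r), dy = dir(1, r), dz = dir(2, r);

    // clip the ray against the grid bounding box (slab method)
    double tmin = -inf, tmax = inf;
    bool miss = false;
    const double o[3] = {ox, oy, oz};
    const double d[3] = {dx, dy, dz};
    const double hi[3] = {bx, by, bz};
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        if (o[a] <= 0.0 || o[a] >= hi[a]) { miss = true; break; }
      } else {
        double t1 = (0.0 - o[a]) / d[a];
        double t2 = (hi[a] - o[a]) / d[a];
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
      }
    }
    if (miss || tmin >= tmax) { out[r] = 0.0; continue; }
    if (tmin < 0.0) tmin = 0.0;

    // entry voxel (nudge inside to avoid landing exactly on a face)
    const double eps = 1e-9 * vs;
    double px = ox + (tmin + eps) * dx;
    double py = oy + (tmin + eps) * dy;
    double pz = oz + (tmin + eps) * dz;
    int i = (int)std::floor(px / vs);
    int j = (int)std::floor(py / vs);
    int k = (int)std::floor(pz / vs);
    if (i < 0) i = 0;
    if (i > nx - 1) i = nx - 1;
    if (j < 0) j = 0;
    if (j > ny - 1) j = ny - 1;
    if (k < 0) k = 0;
    if (k > nz - 1) k = nz - 1;

    // parametric step to the next axis-plane crossing, per axis
    const int si = (dx > 0) - (dx < 0);
    const int sj = (dy > 0) - (dy < 0);
    const int sk = (dz > 0) - (dz < 0);
    double tnx = inf, tny = inf, tnz = inf, dtx = inf, dty = inf, dtz = inf;
    if (si != 0) {
      tnx = (((double)i + (si > 0 ? 1 : 0)) * vs - ox) / dx;
      dtx = vs / std::fabs(dx);
    }
    if (sj != 0) {
      tny = (((double)j + (sj > 0 ? 1 : 0)) * vs - oy) / dy;
      dty = vs / std::fabs(dy);
    }
    if (sk != 0) {
      tnz = (((double)k + (sk > 0 ? 1 : 0)) * vs - oz) / dz;
      dtz = vs / std::fabs(dz);
    }

    double acc = 0.0, tcur = tmin;
    while (tcur < tmax - 1e-12) {
      double tn = tnx;
      int axis = 0;
      if (tny < tn) { tn = tny; axis = 1; }
      if (tnz < tn) { tn = tnz; axis = 2; }
      if (tn > tmax) tn = tmax;
      acc += vol[i + nx * (j + ny * k)] * (tn - tcur);
      tcur = tn;
      if (axis == 0) { i += si; tnx += dtx; }
      else if (axis == 1) { j += sj; tny += dty; }
      else { k += sk; tnz += dtz; }
      if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) break;
    }
    out[r] = acc;
  }
  return out;
}
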