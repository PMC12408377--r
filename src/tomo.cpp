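#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam (telecentric) projector pair operating on one z-slice.
//
// Geometry, in voxel-index units: slice pixel (ix, iy) is centred at
// (ix, iy) with the rotation axis at cx = (nx-1)/2, cy = (ny-1)/2.
// Detector coordinate u has nu = nx bins; rays travel along
// dir(theta) = (cos t, sin t) and enter the volume on the -dir side.
// A sample at (u, s) sits at p = c + (u - u0) * (-sin t, cos t)
//                               + (s - s0) * ( cos t, sin t),
// matching the detector convention u = -x sin t + y cos t.
//
// Occlusion: a ray sample is weighted 1 until the first occluded voxel
// (nearest-neighbour lookup) has been passed, 0 afterwards; the boundary
// sample itself still contributes.  The dose operator uses the identical
// weights and a bilinear *splat*, making it the exact adjoint of the
// bilinear *gather* used in projection (mu = 0).

static inline double bilinear_get(const double* v, int nx, int ny,
                                  double x, double y) {
  if (x < 0.0 || y < 0.0 || x > nx - 1.0 || y > ny - 1.0) return 0.0;
  int ix = (int)std::floor(x), iy = (int)std::floor(y);
  if (ix >= nx - 1) ix = nx - 2;
  if (iy >= ny - 1) iy = ny - 2;
  if (ix < 0) ix = 0;
  if (iy < 0) iy = 0;
  double fx = x - ix, fy = y - iy;
  const double* p = v + (size_t)iy * nx + ix;
  return p[0] * (1 - fx) * (1 - fy) + p[1] * fx * (1 - fy) +
         p[nx] * (1 - fx) * fy + p[nx + 1] * fx * fy;
}

static inline void bilinear_add(double* v, int nx, int ny,
                                double x, double y, double w) {
  if (x < 0.0 || y < 0.0 || x > nx - 1.0 || y > ny - 1.0) return;
  int ix = (int)std::floor(x), iy = (int)std::floor(y);
  if (ix >= nx - 1) ix = nx - 2;
  if (iy >= ny - 1) iy = ny - 2;
  if (ix < 0) ix = 0;
  if (iy < 0) iy = 0;
  double fx = x - ix, fy = y - iy;
  double* p = v + (size_t)iy * nx + ix;
  p[0] += w * (1 - fx) * (1 - fy);
  p[1] += w * fx * (1 - fy);
  p[nx] += w * (1 - fx) * fy;
  p[nx + 1] += w * fx * fy;
}

static inline bool occluded_at(const int* occ, int nx, int ny,
                               double x, double y) {
  if (occ == nullptr) return false;
  int ix = (int)std::lround(x), iy = (int)std::lround(y);
  if (ix < 0 || iy < 0 || ix >= nx || iy >= ny) return false;
  return occ[(size_t)iy * nx + ix] != 0;
}

// [[Rcpp::export]]
NumericMatrix cpp_project_slice(NumericMatrix vol, NumericVector angles,
                                Nullable<IntegerMatrix> occlusion,
                                double step) {
  const int nx = vol.nrow(), ny = vol.ncol();
  const int nu = nx, ns = std::max(nx, ny);
  const int na = angles.size();
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double u0 = 0.5 * (nu - 1), s0 = 0.5 * (ns - 1);

  // column-major R matrix -> row stride nx along y handled via transpose view
  std::vector<double> v((size_t)nx * ny);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix)
      v[(size_t)iy * nx + ix] = vol(ix, iy);
  std::vector<int> occv;
  const int* occ = nullptr;
  if (occlusion.isNotNull()) {
    IntegerMatrix om(occlusion);
    occv.resize((size_t)nx * ny);
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix)
        occv[(size_t)iy * nx + ix] = om(ix, iy);
    occ = occv.data();
  }

  // rays with |u - u0| beyond the inscribed (build) circle are skipped in
  // both operators, keeping the pair adjoint
  const double uMax = 0.5 * std::max(nx, ny) + 1.0;
  NumericMatrix out(nu, na);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int u = 0; u < nu; ++u) {
      const double du = u - u0;
      if (std::fabs(du) > uMax) continue;
      double acc = 0.0;
      for (int s = 0; s < ns; ++s) {
        const double ds = s - s0;
        const double x = cx - du * st + ds * ct;
        const double y = cy + du * ct + ds * st;
        acc += bilinear_get(v.data(), nx, ny, x, y);
        if (occ && occluded_at(occ, nx, ny, x, y)) break;
      }
      out(u, a) = acc * step;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_dose_slice(NumericMatrix proj, NumericVector angles,
                             Nullable<IntegerMatrix> occlusion,
                             int nx, int ny, double step, double mu) {
  const int nu = proj.nrow(), na = proj.ncol();
  const int ns = std::max(nx, ny);
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double u0 = 0.5 * (nu - 1), s0 = 0.5 * (ns - 1);

  std::vector<int> occv;
  const int* occ = nullptr;
  if (occlusion.isNotNull()) {
    IntegerMatrix om(occlusion);
    occv.resize((size_t)nx * ny);
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix)
        occv[(size_t)iy * nx + ix] = om(ix, iy);
    occ = occv.data();
  }

  const double uMax = 0.5 * std::max(nx, ny) + 1.0;
  std::vector<double> dose((size_t)nx * ny, 0.0);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int u = 0; u < nu; ++u) {
      const double du = u - u0;
      if (std::fabs(du) > uMax) continue;
      const double pv = proj(u, a);
      if (pv == 0.0) continue;
      double att = 1.0;
      const double dec = (mu > 0.0) ? std::exp(-mu * step) : 1.0;
      for (int s = 0; s < ns; ++s) {
        const double ds = s - s0;
        const double x = cx - du * st + ds * ct;
        const double y = cy + du * ct + ds * st;
        bilinear_add(dose.data(), nx, ny, x, y, pv * step * att);
        if (occ && occluded_at(occ, nx, ny, x, y)) break;
        att *= dec;
      }
    }
  }
  NumericMatrix out(nx, ny);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix)
      out(ix, iy) = dose[(size_t)iy * nx + ix];
  return out;
}

// Trilinear sampling of a 3D volume at fractional voxel indices (0-based).
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  const double* v = vol.begin();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[i] = 0.0;
      continue;
    }
    int ix = std::min((int)std::floor(x), nx - 2);
    int iy = std::min((int)std::floor(y), ny - 2);
    int iz = std::min((int)std::floor(z), nz - 2);
    if (ix < 0) ix = 0;
    if (iy < 0) iy = 0;
    if (iz < 0) iz = 0;
    double fx = x - ix, fy = y - iy, fz = z - iz;
    const size_t sxy = (size_t)nx * ny;
    const double* p = v + iz * sxy + (size_t)iy * nx + ix;
    double c00 = p[0] * (1 - fx) + p[1] * fx;
    double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
    double c01 = p[sxy] * (1 - fx) + p[sxy + 1] * fx;
    double c11 = p[sxy + nx] * (1 - fx) + p[sxy + nx + 1] * fx;
    out[i] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
             (c01 * (1 - fy) + c11 * fy) * fz;
  }
  return out;
}
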