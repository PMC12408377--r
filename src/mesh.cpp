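#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Marching tetrahedra on the Kuhn (Freudenthal) 6-tet decomposition of each
// grid cell.  The decomposition is translation-invariant, so the induced
// triangulation agrees across shared cell faces and the extracted surface of
// a closed level set is watertight.  Vertices lie on tet edges where the
// field crosses `iso` and are deduplicated by their (global corner, corner)
// edge key, interpolated linearly (sub-voxel accurate on a true SDF).
// Inside is field < iso; triangles are oriented with outward normals.
// ---------------------------------------------------------------------------

struct MTState {
  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static int edge_vertex(MTState& st, uint64_t ia, uint64_t ib,
                       const double* px, const double* py, const double* pz,
                       const double* fv, double iso,
                       int a, int b) {
  uint64_t key = (ia < ib) ? (ia << 32 | ib) : (ib << 32 | ia);
  auto it = st.edge_vert.find(key);
  if (it != st.edge_vert.end()) return it->second;
  double t = (iso - fv[a]) / (fv[b] - fv[a]);
  // keep vertices off the corners so distinct edge vertices stay distinct
  // even at float32 precision (STL round trips)
  t = std::min(std::max(t, 1e-4), 1.0 - 1e-4);
  int id = (int)st.vx.size();
  st.vx.push_back(px[a] + t * (px[b] - px[a]));
  st.vy.push_back(py[a] + t * (py[b] - py[a]));
  st.vz.push_back(pz[a] + t * (pz[b] - pz[a]));
  st.edge_vert.emplace(key, id);
  return id;
}

static void emit_tri(MTState& st, int a, int b, int c,
                     double ox, double oy, double oz) {
  // orient so the normal points along the inside->outside direction (o)
  double ux = st.vx[b] - st.vx[a], uy = st.vy[b] - st.vy[a],
         uz = st.vz[b] - st.vz[a];
  double wx = st.vx[c] - st.vx[a], wy = st.vy[c] - st.vy[a],
         wz = st.vz[c] - st.vz[a];
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz,
         nz = ux * wy - uy * wx;
  if (nx * ox + ny * oy + nz * oz < 0) std::swap(b, c);
  st.f0.push_back(a);
  st.f1.push_back(b);
  st.f2.push_back(c);
}

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dim,
                    NumericVector origin, double voxel, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* F = field.begin();
  const size_t sxy = (size_t)nx * ny;
  // the 6 Kuhn tets, corners as cube-vertex bit codes (x|y<<1|z<<2)
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  MTState st;
  double px[8], py[8], pz[8], fv[8];
  uint64_t gid[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + (c >> 2);
          size_t idx = ck * sxy + (size_t)cj * nx + ci;
          fv[c] = F[idx];
          // exact-iso corners would spawn duplicate vertices on every
          // incident edge; nudge them off the level set (consistently,
          // since every cell reads the same field value)
          if (fv[c] == iso) fv[c] = iso + 1e-12 * (1.0 + std::fabs(iso));
          gid[c] = (uint64_t)idx;
          px[c] = origin[0] + (ci + 0.5) * voxel;
          py[c] = origin[1] + (cj + 0.5) * voxel;
          pz[c] = origin[2] + (ck + 0.5) * voxel;
          if (fv[c] < iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (fv[T[c]] < iso) in[nin++] = T[c]; else out[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          // inside->outside direction for orientation
          double oxm = 0, oym = 0, ozm = 0;
          for (int c = 0; c < nout; ++c) {
            oxm += px[out[c]]; oym += py[out[c]]; ozm += pz[out[c]];
          }
          oxm /= nout; oym /= nout; ozm /= nout;
          double ixm = 0, iym = 0, izm = 0;
          for (int c = 0; c < nin; ++c) {
            ixm += px[in[c]]; iym += py[in[c]]; izm += pz[in[c]];
          }
          ixm /= nin; iym /= nin; izm /= nin;
          double ox = oxm - ixm, oy = oym - iym, oz = ozm - izm;
          if (nin == 1) {
            int a = edge_vertex(st, gid[in[0]], gid[out[0]], px, py, pz, fv,
                                iso, in[0], out[0]);
            int b = edge_vertex(st, gid[in[0]], gid[out[1]], px, py, pz, fv,
                                iso, in[0], out[1]);
            int c = edge_vertex(st, gid[in[0]], gid[out[2]], px, py, pz, fv,
                                iso, in[0], out[2]);
            emit_tri(st, a, b, c, ox, oy, oz);
          } else if (nin == 3) {
            int a = edge_vertex(st, gid[in[0]], gid[out[0]], px, py, pz, fv,
                                iso, in[0], out[0]);
            int b = edge_vertex(st, gid[in[1]], gid[out[0]], px, py, pz, fv,
                                iso, in[1], out[0]);
            int c = edge_vertex(st, gid[in[2]], gid[out[0]], px, py, pz, fv,
                                iso, in[2], out[0]);
            emit_tri(st, a, b, c, ox, oy, oz);
          } else { // 2 in, 2 out -> quad
            int a = edge_vertex(st, gid[in[0]], gid[out[0]], px, py, pz, fv,
                                iso, in[0], out[0]);
            int b = edge_vertex(st, gid[in[0]], gid[out[1]], px, py, pz, fv,
                                iso, in[0], out[1]);
            int c = edge_vertex(st, gid[in[1]], gid[out[1]], px, py, pz, fv,
                                iso, in[1], out[1]);
            int d = edge_vertex(st, gid[in[1]], gid[out[0]], px, py, pz, fv,
                                iso, in[1], out[0]);
            emit_tri(st, a, b, c, ox, oy, oz);
            emit_tri(st, a, c, d, ox, oy, oz);
          }
        }
      }
  int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
  }
  IntegerMatrix Fc(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fc(i, 0) = st.f0[i] + 1; Fc(i, 1) = st.f1[i] + 1; Fc(i, 2) = st.f2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}

// ---------------------------------------------------------------------------
// BVH over triangles: closest-point distance and ray-parity inside test.
// ---------------------------------------------------------------------------

struct Tri {
  double a[3], b[3], c[3], cen[3];
};
struct BVHNode {
  double lo[3], hi[3];
  int left, right, begin, end; // leaf iff left < 0
};

struct BVH {
  std::vector<Tri> tris;
  std::vector<int> order;
  std::vector<BVHNode> nodes;
};

static int bvh_build(BVH& B, int begin, int end) {
  BVHNode nd;
  for (int k = 0; k < 3; ++k) {
    nd.lo[k] = 1e300; nd.hi[k] = -1e300;
  }
  for (int i = begin; i < end; ++i) {
    const Tri& t = B.tris[B.order[i]];
    for (int k = 0; k < 3; ++k) {
      nd.lo[k] = std::min({nd.lo[k], t.a[k], t.b[k], t.c[k]});
      nd.hi[k] = std::max({nd.hi[k], t.a[k], t.b[k], t.c[k]});
    }
  }
  nd.begin = begin; nd.end = end; nd.left = nd.right = -1;
  int id = (int)B.nodes.size();
  B.nodes.push_back(nd);
  if (end - begin > 8) {
    int axis = 0;
    double best = -1;
    for (int k = 0; k < 3; ++k)
      if (nd.hi[k] - nd.lo[k] > best) { best = nd.hi[k] - nd.lo[k]; axis = k; }
    int mid = (begin + end) / 2;
    std::nth_element(B.order.begin() + begin, B.order.begin() + mid,
                     B.order.begin() + end, [&](int x, int y) {
                       return B.tris[x].cen[axis] < B.tris[y].cen[axis];
                     });
    int l = bvh_build(B, begin, mid);
    int r = bvh_build(B, mid, end);
    B.nodes[id].left = l;
    B.nodes[id].right = r;
  }
  return id;
}

static BVH make_bvh(const NumericMatrix& V, const IntegerMatrix& Fc) {
  BVH B;
  int nf = Fc.nrow();
  B.tris.resize(nf);
  B.order.resize(nf);
  for (int i = 0; i < nf; ++i) {
    B.order[i] = i;
    Tri& t = B.tris[i];
    for (int k = 0; k < 3; ++k) {
      t.a[k] = V(Fc(i, 0) - 1, k);
      t.b[k] = V(Fc(i, 1) - 1, k);
      t.c[k] = V(Fc(i, 2) - 1, k);
      t.cen[k] = (t.a[k] + t.b[k] + t.c[k]) / 3.0;
    }
  }
  B.nodes.reserve(2 * nf / 4 + 4);
  bvh_build(B, 0, nf);
  return B;
}

static double box_dist2(const BVHNode& nd, const double* p) {
  double d2 = 0;
  for (int k = 0; k < 3; ++k) {
    double d = 0;
    if (p[k] < nd.lo[k]) d = nd.lo[k] - p[k];
    else if (p[k] > nd.hi[k]) d = p[k] - nd.hi[k];
    d2 += d * d;
  }
  return d2;
}

static double tri_dist2(const Tri& t, const double* p) {
  // Ericson, real-time collision detection: closest point on triangle
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = t.b[k] - t.a[k];
    ac[k] = t.c[k] - t.a[k];
    ap[k] = p[k] - t.a[k];
  }
  auto dot = [](const double* x, const double* y) {
    return x[0] * y[0] + x[1] * y[1] + x[2] * y[2];
  };
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  double cx, cy, cz;
  if (d1 <= 0 && d2 <= 0) { cx = t.a[0]; cy = t.a[1]; cz = t.a[2]; }
  else {
    double bp[3] = {p[0] - t.b[0], p[1] - t.b[1], p[2] - t.b[2]};
    double d3 = dot(ab, bp), d4 = dot(ac, bp);
    if (d3 >= 0 && d4 <= d3) { cx = t.b[0]; cy = t.b[1]; cz = t.b[2]; }
    else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1 / (d1 - d3);
        cx = t.a[0] + v * ab[0]; cy = t.a[1] + v * ab[1];
        cz = t.a[2] + v * ab[2];
      } else {
        double cp[3] = {p[0] - t.c[0], p[1] - t.c[1], p[2] - t.c[2]};
        double d5 = dot(ab, cp), d6 = dot(ac, cp);
        if (d6 >= 0 && d5 <= d6) { cx = t.c[0]; cy = t.c[1]; cz = t.c[2]; }
        else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double w = d2 / (d2 - d6);
            cx = t.a[0] + w * ac[0]; cy = t.a[1] + w * ac[1];
            cz = t.a[2] + w * ac[2];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              cx = t.b[0] + w * (t.c[0] - t.b[0]);
              cy = t.b[1] + w * (t.c[1] - t.b[1]);
              cz = t.b[2] + w * (t.c[2] - t.b[2]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              cx = t.a[0] + ab[0] * v + ac[0] * w;
              cy = t.a[1] + ab[1] * v + ac[1] * w;
              cz = t.a[2] + ab[2] * v + ac[2] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0] - cx, dy = p[1] - cy, dz = p[2] - cz;
  return dx * dx + dy * dy + dz * dz;
}

static void bvh_closest(const BVH& B, int node, const double* p,
                        double& best2) {
  const BVHNode& nd = B.nodes[node];
  if (box_dist2(nd, p) >= best2) return;
  if (nd.left < 0) {
    for (int i = nd.begin; i < nd.end; ++i)
      best2 = std::min(best2, tri_dist2(B.tris[B.order[i]], p));
    return;
  }
  double dl = box_dist2(B.nodes[nd.left], p);
  double dr = box_dist2(B.nodes[nd.right], p);
  if (dl < dr) {
    bvh_closest(B, nd.left, p, best2);
    bvh_closest(B, nd.right, p, best2);
  } else {
    bvh_closest(B, nd.right, p, best2);
    bvh_closest(B, nd.left, p, best2);
  }
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix pts, NumericMatrix V,
                                  IntegerMatrix Fc) {
  BVH B = make_bvh(V, Fc);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best2 = 1e300;
    bvh_closest(B, 0, p, best2);
    out[i] = std::sqrt(best2);
  }
  return out;
}

// ray/triangle (Moller-Trumbore); returns t or -1; flags near-degenerate hits
static double ray_tri(const Tri& t, const double* o, const double* d,
                      bool& unstable) {
  double e1[3], e2[3];
  for (int k = 0; k < 3; ++k) {
    e1[k] = t.b[k] - t.a[k];
    e2[k] = t.c[k] - t.a[k];
  }
  double pv[3] = {d[1] * e2[2] - d[2] * e2[1], d[2] * e2[0] - d[0] * e2[2],
                  d[0] * e2[1] - d[1] * e2[0]};
  double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
  if (std::fabs(det) < 1e-12) return -1.0;
  double inv = 1.0 / det;
  double tv[3] = {o[0] - t.a[0], o[1] - t.a[1], o[2] - t.a[2]};
  double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
  if (u < 0 || u > 1) {
    unstable = unstable || (u > -1e-9 && u < 0) || (u > 1 && u < 1 + 1e-9);
    return -1.0;
  }
  double qv[3] = {tv[1] * e1[2] - tv[2] * e1[1], tv[2] * e1[0] - tv[0] * e1[2],
                  tv[0] * e1[1] - tv[1] * e1[0]};
  double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
  if (v < 0 || u + v > 1) {
    unstable = unstable || (v > -1e-9 && v < 0) || (u + v > 1 && u + v < 1 + 1e-9);
    return -1.0;
  }
  if (u < 1e-9 || v < 1e-9 || u + v > 1 - 1e-9) unstable = true;
  double tt = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
  return tt;
}

static bool ray_box(const BVHNode& nd, const double* o, const double* inv_d) {
  double t0 = 0, t1 = 1e300;
  for (int k = 0; k < 3; ++k) {
    double ta = (nd.lo[k] - o[k]) * inv_d[k];
    double tb = (nd.hi[k] - o[k]) * inv_d[k];
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta);
    t1 = std::min(t1, tb);
    if (t0 > t1) return false;
  }
  return true;
}

static void bvh_raycount(const BVH& B, int node, const double* o,
                         const double* d, const double* inv_d, int& count,
                         bool& unstable) {
  const BVHNode& nd = B.nodes[node];
  if (!ray_box(nd, o, inv_d)) return;
  if (nd.left < 0) {
    for (int i = nd.begin; i < nd.end; ++i) {
      double t = ray_tri(B.tris[B.order[i]], o, d, unstable);
      if (t > 1e-12) ++count;
      else if (t > -1e-12 && t >= 0) unstable = true;
    }
    return;
  }
  bvh_raycount(B, nd.left, o, d, inv_d, count, unstable);
  bvh_raycount(B, nd.right, o, d, inv_d, count, unstable);
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix pts, NumericMatrix V,
                                 IntegerMatrix Fc) {
  BVH B = make_bvh(V, Fc);
  int n = pts.nrow();
  LogicalVector out(n);
  // fixed pseudo-random fallback directions for unstable (edge-grazing) rays
  const double dirs[5][3] = {{1, 0, 0},
                             {0.276172, 0.651294, 0.706817},
                             {-0.537823, 0.812101, 0.224891},
                             {0.401867, -0.339173, 0.850542},
                             {0.714042, 0.282173, -0.640744}};
  for (int i = 0; i < n; ++i) {
    double o[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    bool inside = false;
    for (int trial = 0; trial < 5; ++trial) {
      const double* d = dirs[trial];
      double inv_d[3];
      for (int k = 0; k < 3; ++k)
        inv_d[k] = (std::fabs(d[k]) < 1e-300) ? 1e300 : 1.0 / d[k];
      int count = 0;
      bool unstable = false;
      bvh_raycount(B, 0, o, d, inv_d, count, unstable);
      inside = (count % 2) == 1;
      if (!unstable) break;
    }
    out[i] = inside;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Tube-network SDF voxelization: union of (possibly tapered) capsules.
// segs: n x 8 matrix (x0 y0 z0 x1 y1 z1 r0 r1) in mm.  Only voxels within
// `band` of a segment surface get exact values; the far field is a large
// positive constant (sufficient for 0-level surface extraction).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_tube_sdf(IntegerVector dim, NumericVector origin,
                           double voxel, NumericMatrix segs, double band,
                           double far_value) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector field((R_xlen_t)nx * ny * nz, far_value);
  double* F = field.begin();
  const size_t sxy = (size_t)nx * ny;
  for (int s = 0; s < segs.nrow(); ++s) {
    double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5);
    double r0 = segs(s, 6), r1 = segs(s, 7);
    double rmax = std::max(r0, r1) + band;
    double lox = std::min(ax, bx) - rmax, hix = std::max(ax, bx) + rmax;
    double loy = std::min(ay, by) - rmax, hiy = std::max(ay, by) + rmax;
    double loz = std::min(az, bz) - rmax, hiz = std::max(az, bz) + rmax;
    int i0 = std::max(0, (int)std::floor((lox - origin[0]) / voxel - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((hix - origin[0]) / voxel - 0.5));
    int j0 = std::max(0, (int)std::floor((loy - origin[1]) / voxel - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((hiy - origin[1]) / voxel - 0.5));
    int k0 = std::max(0, (int)std::floor((loz - origin[2]) / voxel - 0.5));
    int k1 = std::min(nz - 1, (int)std::ceil((hiz - origin[2]) / voxel - 0.5));
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double len2 = ux * ux + uy * uy + uz * uz;
    for (int k = k0; k <= k1; ++k) {
      double pz = origin[2] + (k + 0.5) * voxel;
      for (int j = j0; j <= j1; ++j) {
        double py = origin[1] + (j + 0.5) * voxel;
        for (int i = i0; i <= i1; ++i) {
          double px = origin[0] + (i + 0.5) * voxel;
          double t = 0.0;
          if (len2 > 0) {
            t = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / len2;
            t = std::max(0.0, std::min(1.0, t));
          }
          double qx = ax + t * ux - px, qy = ay + t * uy - py,
                 qz = az + t * uz - pz;
          double d = std::sqrt(qx * qx + qy * qy + qz * qz) -
                     (r0 + t * (r1 - r0));
          double* cell = F + k * sxy + (size_t)j * nx + i;
          if (d < *cell) *cell = d;
        }
      }
    }
  }
  return field;
}
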