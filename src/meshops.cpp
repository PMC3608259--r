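// Compiled mesh kernels: closest point on a triangle mesh, ray-parity
// inside/outside test, column-wise voxelisation, and iso-surface
// extraction by marching tetrahedra (Kuhn 6-tet cube decomposition with
// edge-keyed vertex welding, so the output is watertight).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void sub3(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}

// Ericson, Real-Time Collision Detection, closest point on triangle.
static void closest_pt_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  sub3(b, a, ab); sub3(c, a, ac); sub3(p, a, ap);
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }
  double bp[3]; sub3(p, b, bp);
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3]; sub3(p, c, cp);
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nv = V.nrow(), nf = F.nrow();
  NumericVector dist(np);
  NumericMatrix cp(np, 3);
  // flat copies for speed
  std::vector<double> v(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) v[3 * i + k] = V(i, k);
  std::vector<int> f(3 * nf);
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) f[3 * i + k] = F(i, k) - 1;
  // per-face bounding boxes for pruning
  std::vector<double> blo(3 * nf), bhi(3 * nf);
  for (int i = 0; i < nf; ++i) {
    for (int k = 0; k < 3; ++k) {
      double a = v[3 * f[3 * i] + k], b = v[3 * f[3 * i + 1] + k],
             c = v[3 * f[3 * i + 2] + k];
      blo[3 * i + k] = std::min(a, std::min(b, c));
      bhi[3 * i + k] = std::max(a, std::max(b, c));
    }
  }
  double q[3], best[3], cand[3];
  for (int ip = 0; ip < np; ++ip) {
    for (int k = 0; k < 3; ++k) q[k] = P(ip, k);
    // initialise with the nearest vertex
    double bd2 = R_PosInf;
    for (int i = 0; i < nv; ++i) {
      double d2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = q[k] - v[3 * i + k]; d2 += d * d;
      }
      if (d2 < bd2) { bd2 = d2; for (int k = 0; k < 3; ++k) best[k] = v[3*i+k]; }
    }
    for (int i = 0; i < nf; ++i) {
      double bb2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = 0;
        if (q[k] < blo[3 * i + k]) d = blo[3 * i + k] - q[k];
        else if (q[k] > bhi[3 * i + k]) d = q[k] - bhi[3 * i + k];
        bb2 += d * d;
      }
      if (bb2 >= bd2) continue;
      closest_pt_tri(q, &v[3 * f[3 * i]], &v[3 * f[3 * i + 1]],
                     &v[3 * f[3 * i + 2]], cand);
      double d2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = q[k] - cand[k]; d2 += d * d;
      }
      if (d2 < bd2) { bd2 = d2; for (int k = 0; k < 3; ++k) best[k] = cand[k]; }
    }
    dist[ip] = std::sqrt(bd2);
    for (int k = 0; k < 3; ++k) cp(ip, k) = best[k];
  }
  return List::create(_["dist"] = dist, _["points"] = cp);
}

// Moller-Trumbore ray/triangle; returns t or NA
static inline bool ray_tri(const double* o, const double* d, const double* a,
                           const double* b, const double* c, double& t) {
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  sub3(b, a, e1); sub3(c, a, e2);
  pv[0] = d[1]*e2[2] - d[2]*e2[1];
  pv[1] = d[2]*e2[0] - d[0]*e2[2];
  pv[2] = d[0]*e2[1] - d[1]*e2[0];
  double det = dot3(e1, pv);
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  sub3(o, a, tv);
  double u = dot3(tv, pv) * inv;
  if (u < 0.0 || u > 1.0) return false;
  qv[0] = tv[1]*e1[2] - tv[2]*e1[1];
  qv[1] = tv[2]*e1[0] - tv[0]*e1[2];
  qv[2] = tv[0]*e1[1] - tv[1]*e1[0];
  double w = dot3(d, qv) * inv;
  if (w < 0.0 || u + w > 1.0) return false;
  t = dot3(e2, qv) * inv;
  return t > 1e-12;
}

// [[Rcpp::export]]
LogicalVector cpp_points_inside(NumericMatrix P, NumericMatrix V,
                                IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  // fixed quasi-irrational direction avoids edge-aligned rays on
  // axis-aligned tessellations
  double d[3] = {0.2404871350, 0.5646100542, 0.7895126632};
  LogicalVector inside(np);
  std::vector<double> A(3 * nf), B(3 * nf), C(3 * nf);
  for (int i = 0; i < nf; ++i) {
    for (int k = 0; k < 3; ++k) {
      A[3 * i + k] = V(F(i, 0) - 1, k);
      B[3 * i + k] = V(F(i, 1) - 1, k);
      C[3 * i + k] = V(F(i, 2) - 1, k);
    }
  }
  double o[3], t;
  for (int ip = 0; ip < np; ++ip) {
    for (int k = 0; k < 3; ++k) o[k] = P(ip, k);
    int hits = 0;
    for (int i = 0; i < nf; ++i) {
      if (ray_tri(o, d, &A[3 * i], &B[3 * i], &C[3 * i], t)) ++hits;
    }
    inside[ip] = (hits % 2) == 1;
  }
  return inside;
}

// Occupancy voxelisation: for each (x, y) grid column, collect z crossings
// of the column ray with the mesh and fill voxel centres between pairs.
// [[Rcpp::export]]
NumericVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           IntegerVector dim, NumericVector origin,
                           NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], nf = F.nrow();
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  // slight column jitter so rays never pass exactly through mesh edges
  const double jx = 1.734e-4 * spacing[0], jy = 2.449e-4 * spacing[1];
  std::vector<std::vector<double>> colz(static_cast<size_t>(nx) * ny);
  for (int i = 0; i < nf; ++i) {
    double ax = V(F(i,0)-1,0), ay = V(F(i,0)-1,1), az = V(F(i,0)-1,2);
    double bx = V(F(i,1)-1,0), by = V(F(i,1)-1,1), bz = V(F(i,1)-1,2);
    double cx = V(F(i,2)-1,0), cy = V(F(i,2)-1,1), cz = V(F(i,2)-1,2);
    double xlo = std::min(ax, std::min(bx, cx)), xhi = std::max(ax, std::max(bx, cx));
    double ylo = std::min(ay, std::min(by, cy)), yhi = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::ceil((xlo - origin[0] - jx) / spacing[0]));
    int i1 = std::min(nx - 1, (int)std::floor((xhi - origin[0] - jx) / spacing[0]));
    int j0 = std::max(0, (int)std::ceil((ylo - origin[1] - jy) / spacing[1]));
    int j1 = std::min(ny - 1, (int)std::floor((yhi - origin[1] - jy) / spacing[1]));
    double d = (bx - ax) * (cy - ay) - (cx - ax) * (by - ay);
    if (std::fabs(d) < 1e-14) continue;  // vertical triangle: no area in xy
    for (int ix = i0; ix <= i1; ++ix) {
      double px = origin[0] + ix * spacing[0] + jx;
      for (int jy_ = j0; jy_ <= j1; ++jy_) {
        double py = origin[1] + jy_ * spacing[1] + jy;
        double w0 = ((bx - px) * (cy - py) - (cx - px) * (by - py)) / d;
        double w1 = ((cx - px) * (ay - py) - (ax - px) * (cy - py)) / d;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        colz[static_cast<size_t>(jy_) * nx + ix].push_back(
          w0 * az + w1 * bz + w2 * cz);
      }
    }
  }
  for (int jy_ = 0; jy_ < ny; ++jy_) {
    for (int ix = 0; ix < nx; ++ix) {
      std::vector<double>& zs = colz[static_cast<size_t>(jy_) * nx + ix];
      if (zs.size() < 2) continue;
      std::sort(zs.begin(), zs.end());
      size_t npair = zs.size() / 2;
      for (size_t p = 0; p < npair; ++p) {
        double z1 = zs[2 * p], z2 = zs[2 * p + 1];
        int k0 = std::max(0, (int)std::ceil((z1 - origin[2]) / spacing[2]));
        int k1 = std::min(nz - 1, (int)std::floor((z2 - origin[2]) / spacing[2]));
        for (int k = k0; k <= k1; ++k) {
          out[static_cast<R_xlen_t>(k) * nx * ny +
              static_cast<R_xlen_t>(jy_) * nx + ix] = 1.0;
        }
      }
    }
  }
  return out;
}

// Marching tetrahedra over the Kuhn decomposition. vals is in R array
// order: index = i + nx*(j + ny*k).
// [[Rcpp::export]]
List cpp_isosurface(NumericVector vals, IntegerVector dim,
                    NumericVector origin, NumericVector spacing,
                    double tau) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double vmin = Rcpp::min(vals), vmax = Rcpp::max(vals);
  double eps = 1e-10 * std::max(1.0, vmax - vmin);
  std::vector<double> v(vals.begin(), vals.end());
  for (auto& x : v) if (std::fabs(x - tau) < eps) x = tau + eps;

  // the six Kuhn tetrahedra: vertex bit-codes along axis permutations
  static const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  int tets[6][4];
  for (int p = 0; p < 6; ++p) {
    int code = 0;
    tets[p][0] = 0;
    code |= 1 << perms[p][0]; tets[p][1] = code;
    code |= 1 << perms[p][1]; tets[p][2] = code;
    tets[p][3] = 7;
  }
  std::unordered_map<long long, int> edge_vert;
  std::vector<double> Vx, Vy, Vz;
  std::vector<int> Fv;
  const long long NG = static_cast<long long>(nx) * ny * nz;

  auto gidx = [&](int i, int j, int k) {
    return static_cast<long long>(k) * nx * ny +
           static_cast<long long>(j) * nx + i;
  };
  auto edge_vertex = [&](long long g1, long long g2) {
    long long lo = std::min(g1, g2), hi = std::max(g1, g2);
    long long key = lo * NG + hi;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double v1 = v[lo], v2 = v[hi];
    double t = (tau - v1) / (v2 - v1);
    t = std::min(1.0, std::max(0.0, t));
    int i1 = lo % nx, j1 = (lo / nx) % ny, k1 = lo / (static_cast<long long>(nx) * ny);
    int i2 = hi % nx, j2 = (hi / nx) % ny, k2 = hi / (static_cast<long long>(nx) * ny);
    Vx.push_back(origin[0] + spacing[0] * (i1 + t * (i2 - i1)));
    Vy.push_back(origin[1] + spacing[1] * (j1 + t * (j2 - j1)));
    Vz.push_back(origin[2] + spacing[2] * (k1 + t * (k2 - k1)));
    int id = static_cast<int>(Vx.size());
    edge_vert[key] = id;
    return id;
  };

  long long corner[8];
  double cv[8];
  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int i = 0; i < nx - 1; ++i) {
        for (int c = 0; c < 8; ++c) {
          corner[c] = gidx(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          cv[c] = v[corner[c]];
        }
        for (int p = 0; p < 6; ++p) {
          const int* T = tets[p];
          int above[4], na = 0, nb = 0, below[4];
          for (int m = 0; m < 4; ++m) {
            if (cv[T[m]] > tau) above[na++] = T[m]; else below[nb++] = T[m];
          }
          if (na == 0 || na == 4) continue;
          if (na == 1 || na == 3) {
            int lone = (na == 1) ? above[0] : below[0];
            int other[3], no = 0;
            for (int m = 0; m < 4; ++m) if (T[m] != lone) other[no++] = T[m];
            int va_ = edge_vertex(corner[lone], corner[other[0]]);
            int vb_ = edge_vertex(corner[lone], corner[other[1]]);
            int vc_ = edge_vertex(corner[lone], corner[other[2]]);
            Fv.push_back(va_); Fv.push_back(vb_); Fv.push_back(vc_);
          } else {
            int a = above[0], b = above[1], c2 = below[0], d2 = below[1];
            int v1 = edge_vertex(corner[a], corner[c2]);
            int v2 = edge_vertex(corner[a], corner[d2]);
            int v3 = edge_vertex(corner[b], corner[d2]);
            int v4 = edge_vertex(corner[b], corner[c2]);
            Fv.push_back(v1); Fv.push_back(v2); Fv.push_back(v3);
            Fv.push_back(v1); Fv.push_back(v3); Fv.push_back(v4);
          }
        }
      }
    }
  }
  int nvert = static_cast<int>(Vx.size());
  NumericMatrix VM(nvert, 3);
  for (int i = 0; i < nvert; ++i) {
    VM(i, 0) = Vx[i]; VM(i, 1) = Vy[i]; VM(i, 2) = Vz[i];
  }
  int nfv = static_cast<int>(Fv.size() / 3);
  IntegerMatrix FM(nfv, 3);
  for (int i = 0; i < nfv; ++i) {
    FM(i, 0) = Fv[3 * i]; FM(i, 1) = Fv[3 * i + 1]; FM(i, 2) = Fv[3 * i + 2];
  }
  return List::create(_["vertices"] = VM, _["faces"] = FM);
}
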