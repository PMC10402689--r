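// Ray-mesh geometry kernels: Moller-Trumbore intersection, a uniform-grid
// acceleration structure, segment occlusion, inside/outside parity tests,
// point-to-surface distance, and the per-pixel ray-casting renderer.
// All distances are in the mesh's units (mm throughout the package).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static const double RAY_EPS = 1e-6;   // self-intersection guard along t
static const double DET_EPS = 1e-12;  // parallel / degenerate determinant guard

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(const Vec3& a) { return std::sqrt(dot(a, a)); }

// Moller-Trumbore. Returns t in (RAY_EPS, max_t], or -1 on miss.
// bary (optional out): barycentric (u, v) of the hit w.r.t. (v1, v2).
static double ray_tri(const Vec3& o, const Vec3& d,
                      const Vec3& v0, const Vec3& v1, const Vec3& v2,
                      double max_t, double* bu = nullptr, double* bv = nullptr) {
  Vec3 e1 = v1 - v0, e2 = v2 - v0;
  Vec3 p = cross(d, e2);
  double det = dot(e1, p);
  if (std::fabs(det) < DET_EPS) return -1.0;
  double inv = 1.0 / det;
  Vec3 tv = o - v0;
  double u = dot(tv, p) * inv;
  if (u < -1e-12 || u > 1.0 + 1e-12) return -1.0;
  Vec3 q = cross(tv, e1);
  double v = dot(d, q) * inv;
  if (v < -1e-12 || u + v > 1.0 + 1e-12) return -1.0;
  double t = dot(e2, q) * inv;
  if (t <= RAY_EPS || t > max_t) return -1.0;
  if (bu) *bu = u;
  if (bv) *bv = v;
  return t;
}

struct MeshAccel {
  std::vector<Vec3> V;                 // vertices
  std::vector<int> F;                  // faces, 3 * m, 0-based
  // uniform grid
  Vec3 lo, hi;                         // AABB (slightly padded)
  int nx, ny, nz;
  double cx, cy, cz;                   // cell sizes
  std::vector<int> cell_start;         // CSR offsets, size nx*ny*nz + 1
  std::vector<int> cell_tris;          // triangle ids
  mutable std::vector<int> stamp;      // per-triangle visited stamp
  mutable int stamp_val = 0;

  int ncells() const { return nx * ny * nz; }
  int cell_index(int i, int j, int k) const { return (k * ny + j) * nx + i; }
  int nfaces() const { return (int)F.size() / 3; }
  Vec3 vert(int i) const { return V[i]; }
  void tri(int f, Vec3& a, Vec3& b, Vec3& c) const {
    a = V[F[3 * f]]; b = V[F[3 * f + 1]]; c = V[F[3 * f + 2]];
  }
};

static void build_grid(MeshAccel& M) {
  int m = M.nfaces();
  Vec3 lo(1e300, 1e300, 1e300), hi(-1e300, -1e300, -1e300);
  for (const Vec3& v : M.V) {
    lo.x = std::min(lo.x, v.x); lo.y = std::min(lo.y, v.y); lo.z = std::min(lo.z, v.z);
    hi.x = std::max(hi.x, v.x); hi.y = std::max(hi.y, v.y); hi.z = std::max(hi.z, v.z);
  }
  double pad = 1e-6 + 1e-6 * std::max({hi.x - lo.x, hi.y - lo.y, hi.z - lo.z, 1.0});
  lo = lo - Vec3(pad, pad, pad);
  hi = hi + Vec3(pad, pad, pad);
  int n = std::max(1, std::min(48, (int)std::ceil(std::cbrt((double)std::max(m, 1)))));
  M.lo = lo; M.hi = hi;
  M.nx = M.ny = M.nz = n;
  M.cx = (hi.x - lo.x) / n; M.cy = (hi.y - lo.y) / n; M.cz = (hi.z - lo.z) / n;

  std::vector<std::vector<int>> cells(M.ncells());
  for (int f = 0; f < m; ++f) {
    Vec3 a, b, c; M.tri(f, a, b, c);
    double fx0 = std::min({a.x, b.x, c.x}), fx1 = std::max({a.x, b.x, c.x});
    double fy0 = std::min({a.y, b.y, c.y}), fy1 = std::max({a.y, b.y, c.y});
    double fz0 = std::min({a.z, b.z, c.z}), fz1 = std::max({a.z, b.z, c.z});
    int i0 = std::max(0, std::min(n - 1, (int)((fx0 - lo.x) / M.cx)));
    int i1 = std::max(0, std::min(n - 1, (int)((fx1 - lo.x) / M.cx)));
    int j0 = std::max(0, std::min(n - 1, (int)((fy0 - lo.y) / M.cy)));
    int j1 = std::max(0, std::min(n - 1, (int)((fy1 - lo.y) / M.cy)));
    int k0 = std::max(0, std::min(n - 1, (int)((fz0 - lo.z) / M.cz)));
    int k1 = std::max(0, std::min(n - 1, (int)((fz1 - lo.z) / M.cz)));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          cells[M.cell_index(i, j, k)].push_back(f);
  }
  M.cell_start.assign(M.ncells() + 1, 0);
  for (int c = 0; c < M.ncells(); ++c) M.cell_start[c + 1] = M.cell_start[c] + (int)cells[c].size();
  M.cell_tris.resize(M.cell_start.back());
  for (int c = 0; c < M.ncells(); ++c)
    std::copy(cells[c].begin(), cells[c].end(), M.cell_tris.begin() + M.cell_start[c]);
  M.stamp.assign(m, -1);
  M.stamp_val = 0;
}

// 3D-DDA traversal. mode 0: nearest hit (returns t, sets hit_face/bary);
// mode 1: any hit with t <= max_t (early exit, returns t of the found hit);
// mode 2: count all hits (returns count as double).
static double traverse(const MeshAccel& M, const Vec3& o, const Vec3& d,
                       double max_t, int mode,
                       int* hit_face = nullptr, double* bu = nullptr, double* bv = nullptr) {
  // clip ray to grid AABB
  double t0 = 0.0, t1 = max_t;
  const double* ov = &o.x; const double* dv = &d.x;
  const double* lov = &M.lo.x; const double* hiv = &M.hi.x;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dv[a]) < 1e-15) {
      if (ov[a] < lov[a] || ov[a] > hiv[a]) return (mode == 2) ? 0.0 : -1.0;
    } else {
      double ta = (lov[a] - ov[a]) / dv[a];
      double tb = (hiv[a] - ov[a]) / dv[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
    }
  }
  if (t0 > t1) return (mode == 2) ? 0.0 : -1.0;

  Vec3 p = o + d * std::max(t0, 0.0);
  int i = std::max(0, std::min(M.nx - 1, (int)((p.x - M.lo.x) / M.cx)));
  int j = std::max(0, std::min(M.ny - 1, (int)((p.y - M.lo.y) / M.cy)));
  int k = std::max(0, std::min(M.nz - 1, (int)((p.z - M.lo.z) / M.cz)));
  int si = d.x > 0 ? 1 : -1, sj = d.y > 0 ? 1 : -1, sk = d.z > 0 ? 1 : -1;
  double inf = std::numeric_limits<double>::infinity();
  double tdx = std::fabs(d.x) > 1e-15 ? M.cx / std::fabs(d.x) : inf;
  double tdy = std::fabs(d.y) > 1e-15 ? M.cy / std::fabs(d.y) : inf;
  double tdz = std::fabs(d.z) > 1e-15 ? M.cz / std::fabs(d.z) : inf;
  double tmx = std::fabs(d.x) > 1e-15
      ? ((M.lo.x + (i + (si > 0 ? 1 : 0)) * M.cx) - o.x) / d.x : inf;
  double tmy = std::fabs(d.y) > 1e-15
      ? ((M.lo.y + (j + (sj > 0 ? 1 : 0)) * M.cy) - o.y) / d.y : inf;
  double tmz = std::fabs(d.z) > 1e-15
      ? ((M.lo.z + (k + (sk > 0 ? 1 : 0)) * M.cz) - o.z) / d.z : inf;

  M.stamp_val++;
  double best_t = -1.0; int best_f = -1; double best_u = 0, best_v = 0;
  double count = 0.0;
  while (true) {
    int c = M.cell_index(i, j, k);
    for (int idx = M.cell_start[c]; idx < M.cell_start[c + 1]; ++idx) {
      int f = M.cell_tris[idx];
      if (M.stamp[f] == M.stamp_val) continue;
      M.stamp[f] = M.stamp_val;
      Vec3 a, b, cc; M.tri(f, a, b, cc);
      double u, v;
      double t = ray_tri(o, d, a, b, cc, max_t, &u, &v);
      if (t > 0) {
        if (mode == 1) return t;
        if (mode == 2) { count += 1.0; continue; }
        if (best_t < 0 || t < best_t) { best_t = t; best_f = f; best_u = u; best_v = v; }
      }
    }
    // early exit for nearest-hit: hit within the already-traversed cells
    double cell_exit = std::min({tmx, tmy, tmz});
    if (mode == 0 && best_t >= 0 && best_t <= cell_exit) break;
    if (tmx <= tmy && tmx <= tmz) {
      i += si; if (i < 0 || i >= M.nx) break; tmx += tdx;
    } else if (tmy <= tmz) {
      j += sj; if (j < 0 || j >= M.ny) break; tmy += tdy;
    } else {
      k += sk; if (k < 0 || k >= M.nz) break; tmz += tdz;
    }
    if (cell_exit > t1) break;
  }
  if (mode == 2) return count;
  if (best_t >= 0) {
    if (hit_face) *hit_face = best_f;
    if (bu) *bu = best_u;
    if (bv) *bv = best_v;
    return best_t;
  }
  return -1.0;
}

// [[Rcpp::export]]
SEXP accel_build_cpp(NumericMatrix V, IntegerMatrix F) {
  MeshAccel* M = new MeshAccel();
  int n = V.nrow(), m = F.nrow();
  M->V.resize(n);
  for (int i = 0; i < n; ++i) M->V[i] = Vec3(V(i, 0), V(i, 1), V(i, 2));
  M->F.resize(3 * m);
  for (int f = 0; f < m; ++f)
    for (int c = 0; c < 3; ++c) M->F[3 * f + c] = F(f, c) - 1;  // 1-based from R
  build_grid(*M);
  XPtr<MeshAccel> ptr(M, true);
  return ptr;
}

// [[Rcpp::export]]
double ray_triangle_single_cpp(NumericVector o, NumericVector d,
                               NumericVector v0, NumericVector v1, NumericVector v2,
                               double max_t) {
  Vec3 a(v0[0], v0[1], v0[2]), b(v1[0], v1[1], v1[2]), c(v2[0], v2[1], v2[2]);
  // degenerate triangle: area below guard -> treated as a miss
  Vec3 e1 = b - a, e2 = c - a;
  if (norm3(cross(e1, e2)) * 0.5 < 1e-12) return -1.0;
  double t = ray_tri(Vec3(o[0], o[1], o[2]), Vec3(d[0], d[1], d[2]), a, b, c, max_t);
  return t;
}

// Nearest hit for a batch of rays; t = Inf on miss, face 0 on miss (1-based else).
// [[Rcpp::export]]
List accel_raycast_cpp(SEXP accel, NumericMatrix origins, NumericMatrix dirs, double max_t) {
  XPtr<MeshAccel> M(accel);
  int n = origins.nrow();
  NumericVector t(n);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    Vec3 o(origins(i, 0), origins(i, 1), origins(i, 2));
    Vec3 d(dirs(i, 0), dirs(i, 1), dirs(i, 2));
    int f = -1;
    double ti = traverse(*M, o, d, max_t, 0, &f);
    if (ti > 0) { t[i] = ti; face[i] = f + 1; }
    else { t[i] = R_PosInf; face[i] = 0; }
  }
  return List::create(_["t"] = t, _["face"] = face);
}

// true iff any triangle blocks the open segment (p, q), ignoring hits within
// eps_end (absolute, mm) of q. The RAY_EPS guard already protects p's end.
// [[Rcpp::export]]
LogicalVector segments_occluded_cpp(SEXP accel, NumericMatrix P, NumericMatrix Q,
                                    double eps_end) {
  XPtr<MeshAccel> M(accel);
  int n = P.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p(P(i, 0), P(i, 1), P(i, 2));
    Vec3 q(Q(i, 0), Q(i, 1), Q(i, 2));
    Vec3 d = q - p;
    double len = norm3(d);
    if (len < 1e-12) { out[i] = false; continue; }
    d = d * (1.0 / len);
    double t = traverse(*M, p, d, len - eps_end, 1);
    out[i] = (t > 0);
  }
  return out;
}

// Parity test: count crossings along the supplied direction per point.
// [[Rcpp::export]]
IntegerVector count_crossings_cpp(SEXP accel, NumericMatrix P, NumericMatrix dirs) {
  XPtr<MeshAccel> M(accel);
  int n = P.nrow();
  IntegerVector out(n);
  double big = 1e12;
  for (int i = 0; i < n; ++i) {
    Vec3 o(P(i, 0), P(i, 1), P(i, 2));
    Vec3 d(dirs(i, 0), dirs(i, 1), dirs(i, 2));
    out[i] = (int)traverse(*M, o, d, big, 2);
  }
  return out;
}

// Unsigned distance from each point to the mesh surface (exact point-triangle).
// [[Rcpp::export]]
NumericVector surface_distance_cpp(SEXP accel, NumericMatrix P) {
  XPtr<MeshAccel> M(accel);
  int n = P.nrow(), m = M->nfaces();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p(P(i, 0), P(i, 1), P(i, 2));
    double best = 1e300;
    for (int f = 0; f < m; ++f) {
      Vec3 a, b, c; M->tri(f, a, b, c);
      // closest point on triangle (Ericson, Real-Time Collision Detection)
      Vec3 ab = b - a, ac = c - a, ap = p - a;
      double d1 = dot(ab, ap), d2 = dot(ac, ap);
      Vec3 cp;
      if (d1 <= 0 && d2 <= 0) cp = a;
      else {
        Vec3 bp = p - b;
        double d3 = dot(ab, bp), d4 = dot(ac, bp);
        if (d3 >= 0 && d4 <= d3) cp = b;
        else {
          double vc = d1 * d4 - d3 * d2;
          if (vc <= 0 && d1 >= 0 && d3 <= 0) cp = a + ab * (d1 / (d1 - d3));
          else {
            Vec3 cpv = p - c;
            double d5 = dot(ab, cpv), d6 = dot(ac, cpv);
            if (d6 >= 0 && d5 <= d6) cp = c;
            else {
              double vb = d5 * d2 - d1 * d6;
              if (vb <= 0 && d2 >= 0 && d6 <= 0) cp = a + ac * (d2 / (d2 - d6));
              else {
                double va = d3 * d6 - d5 * d4;
                if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
                  cp = b + (c - b) * ((d4 - d3) / ((d4 - d3) + (d5 - d6)));
                else {
                  double denom = 1.0 / (va + vb + vc);
                  cp = a + ab * (vb * denom) + ac * (vc * denom);
                }
              }
            }
          }
        }
      }
      double dd = dot(p - cp, p - cp);
      if (dd < best) best = dd;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Per-pixel ray-casting renderer with Phong headlight shading.
// pose: 4x4 model->camera; camera looks down +z, u right, v down,
// pixel ray through (u + 0.5, v + 0.5). Returns image [0,1] and depth (mm,
// Inf on miss), both height x width matrices.
// [[Rcpp::export]]
List render_view_cpp(SEXP accel, NumericMatrix VN, NumericMatrix pose,
                     double fx, double fy, double cx, double cy,
                     int width, int height,
                     double ambient, double diffuse, double specular,
                     double shininess, double att_c, double att_l, double att_q) {
  XPtr<MeshAccel> M(accel);
  // camera->model: R^T, -R^T t
  double R[3][3], tvec[3];
  for (int r = 0; r < 3; ++r) {
    for (int c = 0; c < 3; ++c) R[r][c] = pose(r, c);
    tvec[r] = pose(r, 3);
  }
  Vec3 origin(
    -(R[0][0] * tvec[0] + R[1][0] * tvec[1] + R[2][0] * tvec[2]),
    -(R[0][1] * tvec[0] + R[1][1] * tvec[1] + R[2][1] * tvec[2]),
    -(R[0][2] * tvec[0] + R[1][2] * tvec[1] + R[2][2] * tvec[2]));
  NumericMatrix img(height, width), depth(height, width);
  double big = 1e12;
  bool has_vn = VN.nrow() == (int)M->V.size();
  std::vector<Vec3> vn;
  if (has_vn) {
    vn.resize(VN.nrow());
    for (int i = 0; i < VN.nrow(); ++i) vn[i] = Vec3(VN(i, 0), VN(i, 1), VN(i, 2));
  }
  for (int v = 0; v < height; ++v) {
    for (int u = 0; u < width; ++u) {
      double xc = (u + 0.5 - cx) / fx, yc = (v + 0.5 - cy) / fy, zc = 1.0;
      // rotate cam dir into model space: d = R^T * (xc, yc, zc)
      Vec3 d(R[0][0] * xc + R[1][0] * yc + R[2][0] * zc,
             R[0][1] * xc + R[1][1] * yc + R[2][1] * zc,
             R[0][2] * xc + R[1][2] * yc + R[2][2] * zc);
      double dn = norm3(d);
      d = d * (1.0 / dn);
      int f = -1; double bu = 0, bv = 0;
      double t = traverse(*M, origin, d, big, 0, &f, &bu, &bv);
      if (t < 0) { img(v, u) = 0.0; depth(v, u) = R_PosInf; continue; }
      depth(v, u) = t;
      Vec3 n;
      if (has_vn) {
        int i0 = M->F[3 * f], i1 = M->F[3 * f + 1], i2 = M->F[3 * f + 2];
        double w0 = 1.0 - bu - bv;
        n = vn[i0] * w0 + vn[i1] * bu + vn[i2] * bv;
      } else {
        Vec3 a, b, c; M->tri(f, a, b, c);
        n = cross(b - a, c - a);
      }
      double nn = norm3(n);
      if (nn < 1e-15) { img(v, u) = ambient; continue; }
      n = n * (1.0 / nn);
      // headlight: light and viewer both at the origin; l = -d
      if (dot(n, d) > 0) n = n * (-1.0);  // two-sided shading
      double ndl = std::max(0.0, dot(n, d * (-1.0)));
      double att = 1.0 / (att_c + att_l * t + att_q * t * t);
      // reflect l about n; viewer dir = -d, so r.v = 2*ndl^2 - 1
      double rv = std::max(0.0, 2.0 * ndl * ndl - 1.0);
      double val = ambient + att * (diffuse * ndl + specular * std::pow(rv, shininess));
      img(v, u) = std::min(1.0, std::max(0.0, val));
    }
  }
  return List::create(_["image"] = img, _["depth"] = depth);
}
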