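#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// ---- small dense helpers -------------------------------------------------
// symmetric 3x3 tensors are stored row-wise packed: (xx, xy, xz, yy, yz, zz)

static inline double sym_det(const double *m) {
  return m[0] * (m[3] * m[5] - m[4] * m[4])
       - m[1] * (m[1] * m[5] - m[4] * m[2])
       + m[2] * (m[1] * m[4] - m[3] * m[2]);
}

static inline double sym_quad(const double *m, double x, double y, double z) {
  return m[0] * x * x + m[3] * y * y + m[5] * z * z
       + 2.0 * (m[1] * x * y + m[2] * x * z + m[4] * y * z);
}

static inline double tet_volume(const double *V, int n, int a, int b, int c, int d) {
  double ax = V[a], ay = V[a + n], az = V[a + 2 * n];
  double ux = V[b] - ax, uy = V[b + n] - ay, uz = V[b + 2 * n] - az;
  double vx = V[c] - ax, vy = V[c + n] - ay, vz = V[c + 2 * n] - az;
  double wx = V[d] - ax, wy = V[d + n] - ay, wz = V[d + 2 * n] - az;
  return (ux * (vy * wz - vz * wy)
        - uy * (vx * wz - vz * wx)
        + uz * (vx * wy - vy * wx)) / 6.0;
}

// mean-ratio shape quality of a tet in the metric given by the arithmetic
// mean of its four vertex tensors; clamped to [0, 1], 0 for degenerate tets
static double mean_ratio_q(const double *V, const double *M, int n,
                           int a, int b, int c, int d) {
  double mm[6];
  for (int k = 0; k < 6; ++k)
    mm[k] = 0.25 * (M[a + k * n] + M[b + k * n] + M[c + k * n] + M[d + k * n]);
  double vol = std::fabs(tet_volume(V, n, a, b, c, d));
  if (vol <= 0.0) return 0.0;
  double dm = sym_det(mm);
  if (dm <= 0.0) return 0.0;
  int vid[4] = {a, b, c, d};
  double s = 0.0;
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j) {
      double ex = V[vid[j]] - V[vid[i]];
      double ey = V[vid[j] + n] - V[vid[i] + n];
      double ez = V[vid[j] + 2 * n] - V[vid[i] + 2 * n];
      s += sym_quad(mm, ex, ey, ez);
    }
  if (s <= 0.0) return 0.0;
  double q = (36.0 / std::cbrt(3.0)) * std::pow(vol * std::sqrt(dm), 2.0 / 3.0) / s;
  if (q > 1.0) q = 1.0;
  if (q < 0.0) q = 0.0;
  return q;
}

// Eq.-style interpolated metric edge length from endpoint lengths
static inline double edge_len_interp(double la, double lb) {
  if (std::fabs(la - lb) > 0.001) return (la - lb) / std::log(la / lb);
  return 0.5 * (la + lb);
}

// ---- exported batch kernels ---------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_signed_volumes(NumericMatrix V, IntegerMatrix T) {
  int m = T.nrow(), n = V.nrow();
  NumericVector out(m);
  const double *v = REAL(V);
  for (int i = 0; i < m; ++i)
    out[i] = tet_volume(v, n, T(i, 0) - 1, T(i, 1) - 1, T(i, 2) - 1, T(i, 3) - 1);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_mean_ratio(NumericMatrix V, IntegerMatrix T, NumericMatrix M) {
  int m = T.nrow(), n = V.nrow();
  NumericVector out(m);
  const double *v = REAL(V);
  const double *mm = REAL(M);
  for (int i = 0; i < m; ++i)
    out[i] = mean_ratio_q(v, mm, n, T(i, 0) - 1, T(i, 1) - 1, T(i, 2) - 1, T(i, 3) - 1);
  return out;
}

// metric length per edge: endpoint lengths under each endpoint tensor,
// combined with the log-mean formula (threshold 0.001)
// [[Rcpp::export]]
NumericVector cpp_edge_metric_lengths(NumericMatrix V, IntegerMatrix E, NumericMatrix M) {
  int m = E.nrow(), n = V.nrow();
  NumericVector out(m);
  const double *v = REAL(V);
  const double *mm = REAL(M);
  double ma[6], mb[6];
  for (int i = 0; i < m; ++i) {
    int a = E(i, 0) - 1, b = E(i, 1) - 1;
    double ex = v[b] - v[a], ey = v[b + n] - v[a + n], ez = v[b + 2 * n] - v[a + 2 * n];
    for (int k = 0; k < 6; ++k) { ma[k] = mm[a + k * n]; mb[k] = mm[b + k * n]; }
    double la = std::sqrt(std::max(0.0, sym_quad(ma, ex, ey, ez)));
    double lb = std::sqrt(std::max(0.0, sym_quad(mb, ex, ey, ez)));
    out[i] = edge_len_interp(la, lb);
  }
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb-Huttenlocher) ------

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int len, double step) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e300; z[1] = 1e300;
  double s2 = step * step;
  for (int q = 1; q < len; ++q) {
    double s;
    while (true) {
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) / (2.0 * s2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < len; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = (q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// squared EDT of a 3-D mask: distance from every voxel to the nearest seed
// (mask != 0) voxel center, honoring anisotropic spacing
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dims, NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t ntot = (size_t)nx * ny * nz;
  std::vector<double> g(ntot);
  const double INF = 1e300;
  for (size_t i = 0; i < ntot; ++i) g[i] = mask[i] != 0 ? 0.0 : INF;
  int maxlen = std::max(nx, std::max(ny, nz));
  std::vector<double> f(maxlen), d(maxlen), z(maxlen + 1);
  std::vector<int> v(maxlen);
  // x pass
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky) {
      size_t base = (size_t)ky * nx + (size_t)kz * nx * ny;
      for (int q = 0; q < nx; ++q) f[q] = g[base + q];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int q = 0; q < nx; ++q) g[base + q] = d[q];
    }
  // y pass
  for (int kz = 0; kz < nz; ++kz)
    for (int kx = 0; kx < nx; ++kx) {
      size_t base = (size_t)kx + (size_t)kz * nx * ny;
      for (int q = 0; q < ny; ++q) f[q] = g[base + (size_t)q * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int q = 0; q < ny; ++q) g[base + (size_t)q * nx] = d[q];
    }
  // z pass
  for (int ky = 0; ky < ny; ++ky)
    for (int kx = 0; kx < nx; ++kx) {
      size_t base = (size_t)kx + (size_t)ky * nx;
      for (int q = 0; q < nz; ++q) f[q] = g[base + (size_t)q * nx * ny];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int q = 0; q < nz; ++q) g[base + (size_t)q * nx * ny] = d[q];
    }
  NumericVector out(ntot);
  for (size_t i = 0; i < ntot; ++i) out[i] = g[i];
  return out;
}

// exact directed Hausdorff distance max_a min_b ||a-b|| with early exit
// [[Rcpp::export]]
double cpp_directed_hausdorff(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  const double *a = REAL(A), *b = REAL(B);
  double hd2 = 0.0;
  for (int i = 0; i < na; ++i) {
    double ax = a[i], ay = a[i + na], az = a[i + 2 * na];
    double best = 1e300;
    for (int j = 0; j < nb; ++j) {
      double dx = ax - b[j], dy = ay - b[j + nb], dz = az - b[j + 2 * nb];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        if (best <= hd2) break; // cannot raise the running max
      }
    }
    if (best > hd2) hd2 = best;
  }
  return std::sqrt(hd2);
}

// ---- local reconnection (2-3 and 3-2 flips) ------------------------------

typedef std::unordered_map<uint64_t, std::pair<int, int> > FaceMap;

static inline uint64_t face_key(int a, int b, int c) {
  if (a > b) std::swap(a, b);
  if (b > c) std::swap(b, c);
  if (a > b) std::swap(a, b);
  return ((uint64_t)a << 42) | ((uint64_t)b << 21) | (uint64_t)c;
}

struct MeshWork {
  std::vector<std::array<int, 4> > tets;
  std::vector<char> alive;
  std::vector<int> version, stamp;
  std::vector<char> attempted, lockfail;
  FaceMap faces;
  int n; // vertex count
  const double *V;
  const double *M;

  void face_insert(int t) {
    static const int F[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
    for (int f = 0; f < 4; ++f) {
      uint64_t k = face_key(tets[t][F[f][0]], tets[t][F[f][1]], tets[t][F[f][2]]);
      FaceMap::iterator it = faces.find(k);
      if (it == faces.end()) faces[k] = std::make_pair(t, -1);
      else it->second.second = t;
    }
  }
  void face_remove(int t) {
    static const int F[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
    for (int f = 0; f < 4; ++f) {
      uint64_t k = face_key(tets[t][F[f][0]], tets[t][F[f][1]], tets[t][F[f][2]]);
      FaceMap::iterator it = faces.find(k);
      if (it == faces.end()) continue;
      if (it->second.first == t) it->second.first = it->second.second, it->second.second = -1;
      else if (it->second.second == t) it->second.second = -1;
      if (it->second.first == -1) faces.erase(it);
    }
  }
  int face_other(int a, int b, int c, int self) const {
    FaceMap::const_iterator it = faces.find(face_key(a, b, c));
    if (it == faces.end()) return -1;
    if (it->second.first == self) return it->second.second;
    if (it->second.second == self) return it->second.first;
    return -1;
  }
  double q(int a, int b, int c, int d) const { return mean_ratio_q(V, M, n, a, b, c, d); }
  double qt(int t) const { return q(tets[t][0], tets[t][1], tets[t][2], tets[t][3]); }
  int add_tet(int a, int b, int c, int d, int ver) {
    std::array<int, 4> tt = {{a, b, c, d}};
    if (tet_volume(V, n, a, b, c, d) < 0.0) { tt[0] = b; tt[1] = a; }
    tets.push_back(tt);
    alive.push_back(1);
    version.push_back(ver);
    stamp.push_back(0);
    attempted.push_back(0);
    lockfail.push_back(0);
    int id = (int)tets.size() - 1;
    face_insert(id);
    return id;
  }
};

// One reconnection sweep. mode: 0 = naive, 1 = optimized (change tracking).
// Indices in T are 1-based; state vectors are aligned with rows of T.
// [[Rcpp::export]]
List cpp_reconnection_pass(NumericMatrix V, IntegerMatrix T, NumericMatrix M,
                           IntegerVector version, IntegerVector stamp,
                           IntegerVector attempted, IntegerVector lockfail,
                           int mesh_version, int mode, double q_accept) {
  MeshWork w;
  int m0 = T.nrow();
  w.n = V.nrow();
  w.V = REAL(V);
  w.M = REAL(M);
  w.tets.reserve(m0 * 2);
  for (int i = 0; i < m0; ++i) {
    std::array<int, 4> tt = {{T(i, 0) - 1, T(i, 1) - 1, T(i, 2) - 1, T(i, 3) - 1}};
    w.tets.push_back(tt);
    w.alive.push_back(1);
    w.version.push_back(version[i]);
    w.stamp.push_back(stamp[i]);
    w.attempted.push_back((char)attempted[i]);
    w.lockfail.push_back((char)lockfail[i]);
  }
  for (int i = 0; i < m0; ++i) w.face_insert(i);

  static const int F[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
  static const int ED[6][2] = {{0, 1}, {0, 2}, {0, 3}, {1, 2}, {1, 3}, {2, 3}};
  long attempts = 0, applied = 0, skipped = 0;

  for (int t = 0; t < m0; ++t) {
    if (!w.alive[t]) continue;
    if (mode == 1 && w.attempted[t] && !w.lockfail[t]) {
      // skip iff neither the element nor any face neighbor changed since
      // the last attempt
      bool changed = w.version[t] > w.stamp[t];
      if (!changed) {
        for (int f = 0; f < 4 && !changed; ++f) {
          int nb = w.face_other(w.tets[t][F[f][0]], w.tets[t][F[f][1]], w.tets[t][F[f][2]], t);
          if (nb >= 0 && w.version[nb] > w.stamp[t]) changed = true;
        }
      }
      if (!changed) { ++skipped; continue; }
    }
    ++attempts;
    w.attempted[t] = 1;
    w.lockfail[t] = 0;
    w.stamp[t] = mesh_version;
    bool done = false;

    // 2-3 flips across each interior face
    for (int f = 0; f < 4 && !done; ++f) {
      int p = w.tets[t][F[f][0]], qv = w.tets[t][F[f][1]], r = w.tets[t][F[f][2]];
      int nb = w.face_other(p, qv, r, t);
      if (nb < 0) continue;
      int a = w.tets[t][f]; // vertex of t opposite the face
      int b = -1;
      for (int k = 0; k < 4; ++k) {
        int vv = w.tets[nb][k];
        if (vv != p && vv != qv && vv != r) { b = vv; break; }
      }
      if (b < 0) continue;
      // candidate tets around edge (a,b): all three must have consistent
      // nonzero orientation (the 5-point hull must be convex around a-b)
      double va = tet_volume(w.V, w.n, a, b, p, qv);
      double vb = tet_volume(w.V, w.n, a, b, qv, r);
      double vc = tet_volume(w.V, w.n, a, b, r, p);
      double eps = 1e-14;
      bool pos = (va > eps && vb > eps && vc > eps) || (va < -eps && vb < -eps && vc < -eps);
      if (!pos) continue;
      double qold = std::min(w.qt(t), w.qt(nb));
      double qnew = std::min(w.q(a, b, p, qv), std::min(w.q(a, b, qv, r), w.q(a, b, r, p)));
      if (qnew > qold + q_accept) {
        ++mesh_version;
        // bump neighbors of the replaced pair
        int touch[2] = {t, nb};
        for (int s = 0; s < 2; ++s)
          for (int ff = 0; ff < 4; ++ff) {
            int o = w.face_other(w.tets[touch[s]][F[ff][0]], w.tets[touch[s]][F[ff][1]],
                                 w.tets[touch[s]][F[ff][2]], touch[s]);
            if (o >= 0) w.version[o] = mesh_version;
          }
        w.alive[t] = 0; w.alive[nb] = 0;
        w.face_remove(t); w.face_remove(nb);
        w.add_tet(a, b, p, qv, mesh_version);
        w.add_tet(a, b, qv, r, mesh_version);
        w.add_tet(a, b, r, p, mesh_version);
        ++applied;
        done = true;
      }
    }

    // 3-2 flips around each 3-tet interior edge
    for (int e = 0; e < 6 && !done; ++e) {
      int a = w.tets[t][ED[e][0]], b = w.tets[t][ED[e][1]];
      // walk the ring: the two faces of t containing edge (a,b)
      int others[2], no = 0;
      for (int k = 0; k < 4; ++k) {
        int vv = w.tets[t][k];
        if (vv != a && vv != b) others[no++] = vv;
      }
      int p = others[0], r = others[1];
      int t2 = w.face_other(a, b, p, t);
      int t3 = w.face_other(a, b, r, t);
      if (t2 < 0 || t3 < 0 || t2 == t3) continue; // boundary edge or 2-ring
      int q2 = -1;
      for (int k = 0; k < 4; ++k) {
        int vv = w.tets[t2][k];
        if (vv != a && vv != b && vv != p) { q2 = vv; break; }
      }
      if (q2 < 0) continue;
      // ring closes with exactly 3 tets iff t2 and t3 share face (a,b,q2)
      int t3b = w.face_other(a, b, q2, t2);
      if (t3b != t3) continue;
      double qold = std::min(w.qt(t), std::min(w.qt(t2), w.qt(t3)));
      double w1 = tet_volume(w.V, w.n, p, q2, r, a);
      double w2 = tet_volume(w.V, w.n, r, q2, p, b);
      double eps = 1e-14;
      bool pos = (w1 > eps && w2 > eps) || (w1 < -eps && w2 < -eps);
      if (!pos) continue;
      double qnew = std::min(w.q(p, q2, r, a), w.q(r, q2, p, b));
      if (qnew > qold + q_accept) {
        ++mesh_version;
        int touch[3] = {t, t2, t3};
        for (int s = 0; s < 3; ++s)
          for (int ff = 0; ff < 4; ++ff) {
            int o = w.face_other(w.tets[touch[s]][F[ff][0]], w.tets[touch[s]][F[ff][1]],
                                 w.tets[touch[s]][F[ff][2]], touch[s]);
            if (o >= 0) w.version[o] = mesh_version;
          }
        w.alive[t] = 0; w.alive[t2] = 0; w.alive[t3] = 0;
        w.face_remove(t); w.face_remove(t2); w.face_remove(t3);
        w.add_tet(p, q2, r, a, mesh_version);
        w.add_tet(r, q2, p, b, mesh_version);
        ++applied;
        done = true;
      }
    }
  }

  // compact live tets
  int mlive = 0;
  for (size_t i = 0; i < w.tets.size(); ++i) if (w.alive[i]) ++mlive;
  IntegerMatrix Tout(mlive, 4);
  IntegerVector vout(mlive), sout(mlive), aout(mlive), lout(mlive);
  int j = 0;
  for (size_t i = 0; i < w.tets.size(); ++i) {
    if (!w.alive[i]) continue;
    for (int k = 0; k < 4; ++k) Tout(j, k) = w.tets[i][k] + 1;
    vout[j] = w.version[i];
    sout[j] = w.stamp[i];
    aout[j] = w.attempted[i];
    lout[j] = w.lockfail[i];
    ++j;
  }
  return List::create(_["tets"] = Tout, _["version"] = vout, _["stamp"] = sout,
                      _["attempted"] = aout, _["lockfail"] = lout,
                      _["mesh_version"] = mesh_version,
                      _["attempts"] = (double)attempts, _["applied"] = (double)applied,
                      _["skipped"] = (double)skipped);
}

// ---- metric-weighted Laplacian smoothing ---------------------------------

// Moves each interior vertex toward the metric-length-weighted average of its
// edge neighbors; a move is kept only if the min mean-ratio quality over the
// vertex star does not decrease and no incident tet inverts.
// [[Rcpp::export]]
List cpp_smooth_pass(NumericMatrix V, IntegerMatrix T, NumericMatrix M,
                     LogicalVector boundary) {
  int n = V.nrow(), m = T.nrow();
  NumericMatrix Vout = clone(V);
  double *v = REAL(Vout);
  const double *mm = REAL(M);
  // vertex -> incident tets
  std::vector<std::vector<int> > star(n);
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < 4; ++k) star[T(i, k) - 1].push_back(i);
  // vertex -> unique edge neighbors
  std::vector<std::vector<int> > nbr(n);
  for (int i = 0; i < m; ++i)
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        if (a != b) nbr[T(i, a) - 1].push_back(T(i, b) - 1);
  LogicalVector moved(n);
  int nmoved = 0;
  double ma[6], mb[6];
  for (int p = 0; p < n; ++p) {
    if (boundary[p] || star[p].empty()) continue;
    std::vector<int> &nb = nbr[p];
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    double wsum = 0.0, px = 0.0, py = 0.0, pz = 0.0;
    for (size_t j = 0; j < nb.size(); ++j) {
      int q = nb[j];
      double ex = v[q] - v[p], ey = v[q + n] - v[p + n], ez = v[q + 2 * n] - v[p + 2 * n];
      for (int k = 0; k < 6; ++k) { ma[k] = mm[p + k * n]; mb[k] = mm[q + k * n]; }
      double la = std::sqrt(std::max(0.0, sym_quad(ma, ex, ey, ez)));
      double lb = std::sqrt(std::max(0.0, sym_quad(mb, ex, ey, ez)));
      double w = edge_len_interp(la, lb);
      if (w <= 0.0) w = 1e-12;
      wsum += w;
      px += w * v[q]; py += w * v[q + n]; pz += w * v[q + 2 * n];
    }
    if (wsum <= 0.0) continue;
    px /= wsum; py /= wsum; pz /= wsum;
    double ox = v[p], oy = v[p + n], oz = v[p + 2 * n];
    double qmin_old = 2.0;
    for (size_t j = 0; j < star[p].size(); ++j) {
      int t = star[p][j];
      double q = mean_ratio_q(v, mm, n, T(t, 0) - 1, T(t, 1) - 1, T(t, 2) - 1, T(t, 3) - 1);
      if (q < qmin_old) qmin_old = q;
    }
    v[p] = px; v[p + n] = py; v[p + 2 * n] = pz;
    double qmin_new = 2.0;
    bool ok = true;
    for (size_t j = 0; j < star[p].size() && ok; ++j) {
      int t = star[p][j];
      double vol = tet_volume(v, n, T(t, 0) - 1, T(t, 1) - 1, T(t, 2) - 1, T(t, 3) - 1);
      if (vol <= 0.0) { ok = false; break; }
      double q = mean_ratio_q(v, mm, n, T(t, 0) - 1, T(t, 1) - 1, T(t, 2) - 1, T(t, 3) - 1);
      if (q < qmin_new) qmin_new = q;
    }
    if (!ok || qmin_new < qmin_old) {
      v[p] = ox; v[p + n] = oy; v[p + 2 * n] = oz;
    } else if (px != ox || py != oy || pz != oz) {
      moved[p] = true;
      ++nmoved;
    }
  }
  return List::create(_["vertices"] = Vout, _["moved"] = moved, _["n_moved"] = nmoved);
}

// all six dihedral angles (degrees) per tet, from face-normal pairs
// [[Rcpp::export]]
NumericMatrix cpp_dihedral_angles(NumericMatrix V, IntegerMatrix T) {
  int m = T.nrow(), n = V.nrow();
  const double *v = REAL(V);
  NumericMatrix out(m, 6);
  static const int ED[6][2] = {{0, 1}, {0, 2}, {0, 3}, {1, 2}, {1, 3}, {2, 3}};
  for (int i = 0; i < m; ++i) {
    int vid[4] = {T(i, 0) - 1, T(i, 1) - 1, T(i, 2) - 1, T(i, 3) - 1};
    for (int e = 0; e < 6; ++e) {
      int a = vid[ED[e][0]], b = vid[ED[e][1]];
      int c = -1, d = -1;
      for (int k = 0; k < 4; ++k)
        if (vid[k] != a && vid[k] != b) { if (c < 0) c = vid[k]; else d = vid[k]; }
      // dihedral along edge (a,b) between faces (a,b,c) and (a,b,d)
      double ux = v[b] - v[a], uy = v[b + n] - v[a + n], uz = v[b + 2 * n] - v[a + 2 * n];
      double wx = v[c] - v[a], wy = v[c + n] - v[a + n], wz = v[c + 2 * n] - v[a + 2 * n];
      double xx = v[d] - v[a], xy = v[d + n] - v[a + n], xz = v[d + 2 * n] - v[a + 2 * n];
      // components of w, x orthogonal to u
      double uu = ux * ux + uy * uy + uz * uz;
      if (uu <= 0.0) { out(i, e) = NA_REAL; continue; }
      double cw = (wx * ux + wy * uy + wz * uz) / uu;
      double cx = (xx * ux + xy * uy + xz * uz) / uu;
      double w1 = wx - cw * ux, w2 = wy - cw * uy, w3 = wz - cw * uz;
      double x1 = xx - cx * ux, x2 = xy - cx * uy, x3 = xz - cx * uz;
      double nw = std::sqrt(w1 * w1 + w2 * w2 + w3 * w3);
      double nx2 = std::sqrt(x1 * x1 + x2 * x2 + x3 * x3);
      if (nw <= 0.0 || nx2 <= 0.0) { out(i, e) = NA_REAL; continue; }
      double cosang = (w1 * x1 + w2 * x2 + w3 * x3) / (nw * nx2);
      if (cosang > 1.0) cosang = 1.0;
      if (cosang < -1.0) cosang = -1.0;
      out(i, e) = std::acos(cosang) * 180.0 / M_PI;
    }
  }
  return out;
}
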