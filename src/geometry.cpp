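// Exact convex-hull geometry in low dimension (2 <= d <= 6).
//
// The hull is recovered by brute-force supporting-hyperplane enumeration
// over all d-subsets of the points: a subset spans a facet hyperplane iff
// every point lies (weakly) on one side.  Volumes come from a fan
// triangulation anchored at the lexicographically smallest vertex, with
// non-simplicial facets triangulated recursively after an isometric
// projection onto their hyperplane.  Intersection volumes clip each
// simplex of one hull by the facet half-spaces of the other and
// re-measure the clipped cells through vertex enumeration.  All steps are
// combinatorial + dense linear algebra; no external geometry library.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

typedef std::vector<double> Vec;
typedef std::vector<Vec> Pts; // row-major points

struct Facet {
  Vec a;                 // outward unit normal: a.x <= b holds for all points
  double b;
  std::vector<int> pts;  // indices of input points lying on the facet
};

inline double dotv(const Vec& x, const Vec& y) {
  double s = 0.0;
  for (size_t i = 0; i < x.size(); ++i) s += x[i] * y[i];
  return s;
}

// determinant of a k x k matrix (row-major, destroyed), partial pivoting
double detk_raw(double* M, int k) {
  double det = 1.0;
  for (int c = 0; c < k; ++c) {
    int piv = c;
    double best = std::fabs(M[c * k + c]);
    for (int r = c + 1; r < k; ++r) {
      double v = std::fabs(M[r * k + c]);
      if (v > best) { best = v; piv = r; }
    }
    if (best == 0.0) return 0.0;
    if (piv != c) {
      for (int j = 0; j < k; ++j) std::swap(M[c * k + j], M[piv * k + j]);
      det = -det;
    }
    double p = M[c * k + c];
    det *= p;
    for (int r = c + 1; r < k; ++r) {
      double f = M[r * k + c] / p;
      for (int j = c; j < k; ++j) M[r * k + j] -= f * M[c * k + j];
    }
  }
  return det;
}

double detk(std::vector<double> M, int k) { return detk_raw(M.data(), k); }

// solve k x k system A x = rhs (both destroyed); false when singular
bool solvek_raw(double* M, double* rhs, int k, double* x) {
  for (int c = 0; c < k; ++c) {
    int piv = c;
    double best = std::fabs(M[c * k + c]);
    for (int r = c + 1; r < k; ++r) {
      double v = std::fabs(M[r * k + c]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-10) return false;
    if (piv != c) {
      for (int j = 0; j < k; ++j) std::swap(M[c * k + j], M[piv * k + j]);
      std::swap(rhs[c], rhs[piv]);
    }
    double p = M[c * k + c];
    for (int r = c + 1; r < k; ++r) {
      double f = M[r * k + c] / p;
      for (int j = c; j < k; ++j) M[r * k + j] -= f * M[c * k + j];
      rhs[r] -= f * rhs[c];
    }
  }
  for (int r = k - 1; r >= 0; --r) {
    double s = rhs[r];
    for (int j = r + 1; j < k; ++j) s -= M[r * k + j] * x[j];
    x[r] = s / M[r * k + r];
  }
  return true;
}

double diameter_bound(const Pts& X, int d) {
  // cheap over-estimate: diagonal of the bounding box
  if (X.empty()) return 1.0;
  double s = 0.0;
  for (int j = 0; j < d; ++j) {
    double lo = X[0][j], hi = X[0][j];
    for (size_t i = 1; i < X.size(); ++i) {
      lo = std::min(lo, X[i][j]);
      hi = std::max(hi, X[i][j]);
    }
    s += (hi - lo) * (hi - lo);
  }
  double diam = std::sqrt(s);
  return diam > 0 ? diam : 1.0;
}

// unit normal to the hyperplane through the d points X[idx], by cofactor
// expansion of the (d-1) x d difference matrix; false when degenerate
bool hyper_normal(const Pts& X, const std::vector<int>& idx, int d, double diam, Vec& a) {
  double D[30]; // (d-1) x d, d <= 6
  for (int i = 1; i < d; ++i)
    for (int j = 0; j < d; ++j)
      D[(i - 1) * d + j] = X[idx[i]][j] - X[idx[0]][j];
  a.assign(d, 0.0);
  double M[25];
  double sgn = 1.0;
  for (int j = 0; j < d; ++j) {
    int cc = 0;
    for (int c = 0; c < d; ++c) {
      if (c == j) continue;
      for (int r = 0; r < d - 1; ++r) M[r * (d - 1) + cc] = D[r * d + c];
      ++cc;
    }
    a[j] = sgn * detk_raw(M, d - 1);
    sgn = -sgn;
  }
  double nrm = std::sqrt(dotv(a, a));
  double scale = 1.0;
  for (int i = 0; i < d - 1; ++i) scale *= diam;
  if (!(nrm > 1e-12 * scale)) return false;
  for (int j = 0; j < d; ++j) a[j] /= nrm;
  return true;
}

// all supporting hyperplanes (facets) of conv(X) in R^d, deduplicated
std::vector<Facet> hull_facets(const Pts& X, int d) {
  int n = (int)X.size();
  std::vector<Facet> facets;
  if (n < d) return facets;
  double diam = diameter_bound(X, d);
  double tol = 1e-9 * diam;
  std::vector<int> idx(d);
  for (int i = 0; i < d; ++i) idx[i] = i;
  Vec a;
  while (true) {
    if (hyper_normal(X, idx, d, diam, a)) {
      double b = dotv(a, X[idx[0]]);
      double mx = -1e300, mn = 1e300;
      bool both = false;
      for (int i = 0; i < n; ++i) {
        double s = dotv(a, X[i]) - b;
        if (s > mx) mx = s;
        if (s < mn) mn = s;
        if (mx > tol && mn < -tol) { both = true; break; }
      }
      if (!both) {
        Vec aa = a;
        double bb = b;
        if (mx > tol) { // points sit above the plane: flip to outward form
          for (int j = 0; j < d; ++j) aa[j] = -aa[j];
          bb = -bb;
        }
        bool dup = false;
        for (const Facet& f : facets) {
          if (dotv(f.a, aa) > 1.0 - 1e-7 && std::fabs(f.b - bb) <= 20 * tol) { dup = true; break; }
        }
        if (!dup) {
          Facet f;
          f.a = aa;
          f.b = bb;
          facets.push_back(f);
        }
      }
    }
    int p = d - 1;
    while (p >= 0 && idx[p] == n - d + p) --p;
    if (p < 0) break;
    ++idx[p];
    for (int q = p + 1; q < d; ++q) idx[q] = idx[q - 1] + 1;
  }
  for (Facet& f : facets) {
    for (int i = 0; i < n; ++i) {
      double s = dotv(f.a, X[i]) - f.b;
      if (std::fabs(s) <= 20 * tol) f.pts.push_back(i);
    }
  }
  return facets;
}

int affine_rank(const Pts& X, int d, double diam) {
  // modified Gram-Schmidt on the difference vectors
  std::vector<Vec> basis;
  double tol = 1e-9 * diam;
  for (size_t i = 1; i < X.size(); ++i) {
    Vec v(d);
    for (int j = 0; j < d; ++j) v[j] = X[i][j] - X[0][j];
    for (const Vec& u : basis) {
      double p = dotv(v, u);
      for (int j = 0; j < d; ++j) v[j] -= p * u[j];
    }
    double nrm = std::sqrt(dotv(v, v));
    if (nrm > tol) {
      for (int j = 0; j < d; ++j) v[j] /= nrm;
      basis.push_back(v);
      if ((int)basis.size() == d) break;
    }
  }
  return (int)basis.size();
}

std::vector<std::vector<int>> tri_simplices(const Pts& X, int k);

// triangulated facets of conv(X) in R^k: list of k-tuples of point indices
std::vector<std::vector<int>> tri_facets(const Pts& X, int k) {
  std::vector<std::vector<int>> out;
  int n = (int)X.size();
  if (k == 1) {
    int imin = 0, imax = 0;
    for (int i = 1; i < n; ++i) {
      if (X[i][0] < X[imin][0]) imin = i;
      if (X[i][0] > X[imax][0]) imax = i;
    }
    out.push_back(std::vector<int>(1, imin));
    if (imax != imin) out.push_back(std::vector<int>(1, imax));
    return out;
  }
  std::vector<Facet> facets = hull_facets(X, k);
  for (const Facet& f : facets) {
    if ((int)f.pts.size() == k) {
      out.push_back(f.pts);
    } else if ((int)f.pts.size() > k) {
      // non-simplicial facet: project onto an orthonormal basis of the
      // hyperplane and triangulate the (k-1)-dimensional image
      std::vector<Vec> B;
      for (int j = 0; j < k && (int)B.size() < k - 1; ++j) {
        Vec v(k, 0.0);
        v[j] = 1.0;
        double pa = dotv(v, f.a);
        for (int t = 0; t < k; ++t) v[t] -= pa * f.a[t];
        for (const Vec& u : B) {
          double p = dotv(v, u);
          for (int t = 0; t < k; ++t) v[t] -= p * u[t];
        }
        double nn = std::sqrt(dotv(v, v));
        if (nn > 1e-8) {
          for (int t = 0; t < k; ++t) v[t] /= nn;
          B.push_back(v);
        }
      }
      if ((int)B.size() < k - 1) continue; // numerically flat, contributes nothing
      Pts Y(f.pts.size(), Vec(k - 1));
      for (size_t i = 0; i < f.pts.size(); ++i)
        for (int c = 0; c < k - 1; ++c) {
          double s = 0.0;
          for (int t = 0; t < k; ++t) s += (X[f.pts[i]][t] - X[f.pts[0]][t]) * B[c][t];
          Y[i][c] = s;
        }
      std::vector<std::vector<int>> sub = tri_simplices(Y, k - 1);
      for (const std::vector<int>& s : sub) {
        std::vector<int> g;
        g.reserve(s.size());
        for (int id : s) g.push_back(f.pts[id]);
        out.push_back(g);
      }
    }
  }
  return out;
}

// fan triangulation of conv(X) in R^k into k-simplices ((k+1)-tuples)
std::vector<std::vector<int>> tri_simplices(const Pts& X, int k) {
  std::vector<std::vector<int>> out;
  int n = (int)X.size();
  if (n < k + 1) return out;
  int apex = 0;
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      if (X[i][j] < X[apex][j]) { apex = i; break; }
      if (X[i][j] > X[apex][j]) break;
    }
  }
  std::vector<std::vector<int>> tf = tri_facets(X, k);
  for (const std::vector<int>& t : tf) {
    if (std::find(t.begin(), t.end(), apex) != t.end()) continue;
    std::vector<int> s;
    s.reserve(t.size() + 1);
    s.push_back(apex);
    for (int id : t) s.push_back(id);
    out.push_back(s);
  }
  return out;
}

double simplex_vol(const Pts& X, const std::vector<int>& s, int k) {
  std::vector<double> M((size_t)k * k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      M[(size_t)i * k + j] = X[s[i + 1]][j] - X[s[0]][j];
  double fact = 1.0;
  for (int i = 2; i <= k; ++i) fact *= i;
  return std::fabs(detk(M, k)) / fact;
}

double hull_volume_impl(const Pts& X, int k) {
  if ((int)X.size() < k + 1) return 0.0;
  if (affine_rank(X, k, diameter_bound(X, k)) < k) return 0.0;
  std::vector<std::vector<int>> tris = tri_simplices(X, k);
  double v = 0.0;
  for (const std::vector<int>& s : tris) v += simplex_vol(X, s, k);
  return v;
}

// volume of the convex cell {x : a_i . x <= b_i} for a small constraint
// set (here: the pooled facets of two simplices), by brute-force vertex
// enumeration over all d-subsets of the constraints
double cell_volume(const std::vector<const Facet*>& C, int d, double tol) {
  int m = (int)C.size();
  if (m < d + 1) return 0.0;
  Pts verts;
  int idx[8];
  for (int i = 0; i < d; ++i) idx[i] = i;
  double M[36], rhs[6], x[6];
  double dedup2 = (10 * tol) * (10 * tol);
  while (true) {
    for (int i = 0; i < d; ++i) {
      for (int j = 0; j < d; ++j) M[i * d + j] = C[idx[i]]->a[j];
      rhs[i] = C[idx[i]]->b;
    }
    if (solvek_raw(M, rhs, d, x)) {
      bool ok = true;
      for (int i = 0; i < m; ++i) {
        double s = -C[i]->b;
        for (int j = 0; j < d; ++j) s += C[i]->a[j] * x[j];
        if (s > tol) { ok = false; break; }
      }
      if (ok) {
        bool dup = false;
        for (const Vec& v : verts) {
          double dd = 0.0;
          for (int j = 0; j < d; ++j) { double e = v[j] - x[j]; dd += e * e; }
          if (dd <= dedup2) { dup = true; break; }
        }
        if (!dup) verts.push_back(Vec(x, x + d));
      }
    }
    int p = d - 1;
    while (p >= 0 && idx[p] == m - d + p) --p;
    if (p < 0) break;
    ++idx[p];
    for (int q = p + 1; q < d; ++q) idx[q] = idx[q - 1] + 1;
  }
  if ((int)verts.size() < d + 1) return 0.0;
  return hull_volume_impl(verts, d);
}

Pts as_points(const NumericMatrix& X) {
  int n = X.nrow(), d = X.ncol();
  Pts P((size_t)n, Vec(d));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j)
      P[i][j] = X(i, j);
  return P;
}

void check_dim(const NumericMatrix& X) {
  if (X.ncol() < 1 || X.ncol() > 6)
    stop("convex-hull routines support 1 to 6 dimensions, got %d", X.ncol());
  for (int i = 0; i < X.nrow(); ++i)
    for (int j = 0; j < X.ncol(); ++j)
      if (!R_finite(X(i, j))) stop("non-finite coordinate at row %d", i + 1);
}

} // namespace

// [[Rcpp::export(name = ".chull_volume_cpp")]]
double chull_volume_cpp(NumericMatrix X) {
  check_dim(X);
  Pts P = as_points(X);
  return hull_volume_impl(P, X.ncol());
}

// [[Rcpp::export(name = ".chull_hrep_cpp")]]
List chull_hrep_cpp(NumericMatrix X) {
  check_dim(X);
  Pts P = as_points(X);
  int d = X.ncol();
  std::vector<Facet> facets = hull_facets(P, d);
  int m = (int)facets.size();
  NumericMatrix A(m, d);
  NumericVector b(m);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < d; ++j) A(i, j) = facets[i].a[j];
    b[i] = facets[i].b;
  }
  return List::create(_["A"] = A, _["b"] = b);
}

// [[Rcpp::export(name = ".chull_vertices_cpp")]]
IntegerVector chull_vertices_cpp(NumericMatrix X) {
  check_dim(X);
  Pts P = as_points(X);
  int d = X.ncol();
  std::vector<std::vector<int>> tf = tri_facets(P, d);
  std::vector<bool> seen(X.nrow(), false);
  for (const std::vector<int>& t : tf)
    for (int id : t) seen[id] = true;
  std::vector<int> out;
  for (int i = 0; i < X.nrow(); ++i)
    if (seen[i]) out.push_back(i + 1);
  return wrap(out);
}

// [[Rcpp::export(name = ".chull_intersection_cpp")]]
double chull_intersection_cpp(NumericMatrix XA, NumericMatrix XB) {
  check_dim(XA);
  check_dim(XB);
  if (XA.ncol() != XB.ncol()) stop("point sets live in different dimensions");
  int d = XA.ncol();
  Pts A = as_points(XA), B = as_points(XB);
  double diam = std::max(diameter_bound(A, d), diameter_bound(B, d));
  double tol = 1e-9 * diam;
  // triangulate both hulls; the intersection volume is the sum of the
  // simplex-simplex intersection volumes, and each of those is a clip of
  // one simplex by at most d + 1 half-spaces (no combinatorial blow-up)
  std::vector<std::vector<int>> trisA = tri_simplices(A, d);
  std::vector<std::vector<int>> trisB = tri_simplices(B, d);
  int nA = (int)trisA.size(), nB = (int)trisB.size();
  std::vector<Pts> SA(nA), SB(nB);
  for (int i = 0; i < nA; ++i) {
    SA[i].assign((size_t)d + 1, Vec(d));
    for (int v = 0; v <= d; ++v) SA[i][v] = A[trisA[i][v]];
  }
  for (int i = 0; i < nB; ++i) {
    SB[i].assign((size_t)d + 1, Vec(d));
    for (int v = 0; v <= d; ++v) SB[i][v] = B[trisB[i][v]];
  }
  // bounding boxes for cheap pair rejection
  std::vector<Vec> loA(nA, Vec(d)), hiA(nA, Vec(d)), loB(nB, Vec(d)), hiB(nB, Vec(d));
  for (int i = 0; i < nA; ++i)
    for (int j = 0; j < d; ++j) {
      double lo = SA[i][0][j], hi = lo;
      for (int v = 1; v <= d; ++v) {
        lo = std::min(lo, SA[i][v][j]);
        hi = std::max(hi, SA[i][v][j]);
      }
      loA[i][j] = lo; hiA[i][j] = hi;
    }
  for (int i = 0; i < nB; ++i)
    for (int j = 0; j < d; ++j) {
      double lo = SB[i][0][j], hi = lo;
      for (int v = 1; v <= d; ++v) {
        lo = std::min(lo, SB[i][v][j]);
        hi = std::max(hi, SB[i][v][j]);
      }
      loB[i][j] = lo; hiB[i][j] = hi;
    }
  // facet half-spaces of every simplex, precomputed once
  std::vector<std::vector<Facet>> FA(nA), FB(nB);
  for (int i = 0; i < nA; ++i) FA[i] = hull_facets(SA[i], d);
  for (int i = 0; i < nB; ++i) FB[i] = hull_facets(SB[i], d);
  double vol = 0.0;
  std::vector<const Facet*> C;
  for (int ia = 0; ia < nA; ++ia) {
    for (int ib = 0; ib < nB; ++ib) {
      bool apart = false;
      for (int j = 0; j < d; ++j) {
        if (loA[ia][j] > hiB[ib][j] + tol || loB[ib][j] > hiA[ia][j] + tol) {
          apart = true;
          break;
        }
      }
      if (apart) continue;
      bool empty = false, cut = false;
      for (const Facet& f : FB[ib]) {
        double mn = 1e300, mx = -1e300;
        for (int v = 0; v <= d; ++v) {
          double sv = dotv(f.a, SA[ia][v]) - f.b;
          mn = std::min(mn, sv);
          mx = std::max(mx, sv);
        }
        if (mn > tol) { empty = true; break; } // A-simplex wholly outside
        if (mx > tol) cut = true;
      }
      if (empty) continue;
      if (!cut) { // A-simplex wholly inside this B simplex
        std::vector<int> id(d + 1);
        for (int v = 0; v <= d; ++v) id[v] = v;
        vol += simplex_vol(SA[ia], id, d);
        continue;
      }
      C.clear();
      for (const Facet& f : FA[ia]) C.push_back(&f);
      for (const Facet& f : FB[ib]) C.push_back(&f);
      vol += cell_volume(C, d, tol);
    }
  }
  return vol;
}
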