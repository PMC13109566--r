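#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Brute-force and grid-hashed neighbourhood kernels for 3-D point clouds.
// Coordinates are metres; all indices crossing the R boundary are 1-based.

static inline double dist2(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// Farthest-point sampling: first index = start (1-based); each subsequent
// pick maximises the minimum distance to the selected set, ties going to
// the lowest index. Returns indices in selection order.
// [[Rcpp::export]]
IntegerVector cpp_fps(NumericMatrix coords, int m, int start) {
  const int n = coords.nrow();
  if (m < 1 || m > n) stop("m must be in [1, nrow(coords)]");
  if (start < 1 || start > n) stop("start index out of range");
  std::vector<double> pts(3 * n);
  for (int i = 0; i < n; ++i) {
    pts[3 * i] = coords(i, 0); pts[3 * i + 1] = coords(i, 1); pts[3 * i + 2] = coords(i, 2);
  }
  IntegerVector out(m);
  std::vector<double> mind(n, R_PosInf);
  int cur = start - 1;
  out[0] = cur + 1;
  for (int s = 1; s < m; ++s) {
    const double* p = &pts[3 * cur];
    int best = -1; double bestd = -1.0;
    for (int i = 0; i < n; ++i) {
      double d = dist2(&pts[3 * i], p);
      if (d < mind[i]) mind[i] = d;
      if (mind[i] > bestd) { bestd = mind[i]; best = i; }
    }
    cur = best;
    out[s] = cur + 1;
    mind[cur] = 0.0;  // never re-selected
  }
  return out;
}


struct Grid {
  double cell, x0, y0, z0;
  std::unordered_map<long long, std::vector<int> > cells;
  const std::vector<double>* pts;
  long long key(int ix, int iy, int iz) const {
    return ((long long)ix + 1048576LL) +
           2097152LL * (((long long)iy + 1048576LL) +
           2097152LL * ((long long)iz + 1048576LL));
  }
  void build(const std::vector<double>& p, int n, double cellsize) {
    pts = &p; cell = cellsize;
    x0 = y0 = z0 = R_PosInf;
    for (int i = 0; i < n; ++i) {
      x0 = std::min(x0, p[3 * i]); y0 = std::min(y0, p[3 * i + 1]); z0 = std::min(z0, p[3 * i + 2]);
    }
    for (int i = 0; i < n; ++i) {
      int ix = (int)std::floor((p[3 * i] - x0) / cell);
      int iy = (int)std::floor((p[3 * i + 1] - y0) / cell);
      int iz = (int)std::floor((p[3 * i + 2] - z0) / cell);
      cells[key(ix, iy, iz)].push_back(i);
    }
  }
  // indices within radius of q (includes any point at distance 0)
  void query(const double* q, double radius, std::vector<std::pair<double, int> >& out) const {
    out.clear();
    double r2 = radius * radius;
    int ix = (int)std::floor((q[0] - x0) / cell);
    int iy = (int)std::floor((q[1] - y0) / cell);
    int iz = (int)std::floor((q[2] - z0) / cell);
    int span = (int)std::ceil(radius / cell);
    const std::vector<double>& p = *pts;
    for (int a = ix - span; a <= ix + span; ++a)
      for (int b = iy - span; b <= iy + span; ++b)
        for (int c = iz - span; c <= iz + span; ++c) {
          auto it = cells.find(key(a, b, c));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            double d = dist2(&p[3 * j], q);
            if (d <= r2) out.push_back(std::make_pair(d, j));
          }
        }
  }
};

// Candidate gathering over the Chebyshev shell of exactly `s` cells.
static void gather_shell(const Grid& g, const std::vector<double>& p,
                         const double* q, int ix, int iy, int iz, int s,
                         std::vector<std::pair<double, int> >& out) {
  for (int a = ix - s; a <= ix + s; ++a)
    for (int b = iy - s; b <= iy + s; ++b)
      for (int c = iz - s; c <= iz + s; ++c) {
        if (std::max(std::abs(a - ix), std::max(std::abs(b - iy), std::abs(c - iz))) != s)
          continue;
        auto it = g.cells.find(g.key(a, b, c));
        if (it == g.cells.end()) continue;
        for (int j : it->second)
          out.push_back(std::make_pair(dist2(&p[3 * j], q), j));
      }
}

// k nearest neighbours (self excluded), nearest-first. Small clouds use
// brute force with partial selection; larger ones a uniform-grid search
// with expanding cell rings.
// [[Rcpp::export]]
List cpp_knn(NumericMatrix coords, int k) {
  const int n = coords.nrow();
  if (k < 1 || k > n - 1) stop("k must be in [1, n - 1]");
  IntegerMatrix idx(n, k);
  NumericMatrix d2(n, k);
  std::vector<double> pts(3 * n);
  for (int i = 0; i < n; ++i) {
    pts[3 * i] = coords(i, 0); pts[3 * i + 1] = coords(i, 1); pts[3 * i + 2] = coords(i, 2);
  }
  if (n <= 2000) {
    std::vector<std::pair<double, int> > cand(n);
    for (int i = 0; i < n; ++i) {
      int nc = 0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        cand[nc++] = std::make_pair(dist2(&pts[3 * j], &pts[3 * i]), j);
      }
      std::partial_sort(cand.begin(), cand.begin() + k, cand.begin() + nc);
      for (int t = 0; t < k; ++t) { idx(i, t) = cand[t].second + 1; d2(i, t) = cand[t].first; }
    }
    return List::create(_["idx"] = idx, _["d2"] = d2);
  }
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], pts[3 * i + d]);
      hi[d] = std::max(hi[d], pts[3 * i + d]);
    }
  double maxext = std::max(hi[0] - lo[0], std::max(hi[1] - lo[1], hi[2] - lo[2]));
  if (maxext <= 0) maxext = 1.0;
  double cell = maxext / std::cbrt((double)n) * std::cbrt((double)k);
  Grid g; g.build(pts, n, cell);
  std::vector<std::pair<double, int> > cand;
  for (int i = 0; i < n; ++i) {
    const double* q = &pts[3 * i];
    int ix = (int)std::floor((q[0] - g.x0) / cell);
    int iy = (int)std::floor((q[1] - g.y0) / cell);
    int iz = (int)std::floor((q[2] - g.z0) / cell);
    cand.clear();
    int s = 0;
    for (;; ++s) {
      gather_shell(g, pts, q, ix, iy, iz, s, cand);
      if ((int)cand.size() > k) {  // > k: the point itself is among candidates
        std::nth_element(cand.begin(), cand.begin() + k, cand.end());
        // all points with distance < s*cell are collected after shell s
        double guaranteed = (double)(s) * cell;
        if (s >= 1 && cand[k].first < guaranteed * guaranteed) break;
      }
      if (s > 2097150) stop("knn grid search failed to converge");
    }
    std::partial_sort(cand.begin(), cand.begin() + std::min((size_t)(k + 1), cand.size()), cand.end());
    int t = 0;
    for (size_t c = 0; c < cand.size() && t < k; ++c) {
      if (cand[c].second == i) continue;
      idx(i, t) = cand[c].second + 1; d2(i, t) = cand[c].first; ++t;
    }
    if (t < k) stop("internal knn error: fewer than k neighbours collected");
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}

// Ball query: for each center (index into coords), up to max_neighbors points
// within radius, nearest-first (the center itself sorts first at distance 0,
// ties by index); empty-ball fallback is the center alone.
// [[Rcpp::export]]
List cpp_ball_query(NumericMatrix coords, IntegerVector centers, double radius,
                    int max_neighbors) {
  const int n = coords.nrow(), nc = centers.size();
  if (radius <= 0) stop("radius must be positive");
  if (max_neighbors < 1) stop("max_neighbors must be >= 1");
  std::vector<double> pts(3 * n);
  for (int i = 0; i < n; ++i) {
    pts[3 * i] = coords(i, 0); pts[3 * i + 1] = coords(i, 1); pts[3 * i + 2] = coords(i, 2);
  }
  Grid g; g.build(pts, n, radius);
  List idx_out(nc), d_out(nc);
  std::vector<std::pair<double, int> > hits;
  for (int c = 0; c < nc; ++c) {
    int ci = centers[c] - 1;
    if (ci < 0 || ci >= n) stop("center index out of range");
    g.query(&pts[3 * ci], radius, hits);
    // ensure the center sorts first among distance ties
    for (auto& h : hits) if (h.second == ci) h.first = -1.0;
    std::sort(hits.begin(), hits.end());
    int keep = std::min((int)hits.size(), max_neighbors);
    if (keep == 0) {  // cannot happen (center is its own hit) but stay safe
      idx_out[c] = IntegerVector::create(ci + 1);
      d_out[c] = NumericVector::create(0.0);
      continue;
    }
    IntegerVector ii(keep); NumericVector dd(keep);
    for (int t = 0; t < keep; ++t) {
      ii[t] = hits[t].second + 1;
      dd[t] = hits[t].first < 0 ? 0.0 : std::sqrt(hits[t].first);
    }
    idx_out[c] = ii; d_out[c] = dd;
  }
  return List::create(_["idx"] = idx_out, _["dist"] = d_out);
}

// Nearest distance from each query row to any reference row.
// [[Rcpp::export]]
NumericVector cpp_min_cross_dist(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  std::vector<double> q(3 * nq), r(3 * nr);
  for (int i = 0; i < nq; ++i) {
    q[3 * i] = query(i, 0); q[3 * i + 1] = query(i, 1); q[3 * i + 2] = query(i, 2);
  }
  for (int i = 0; i < nr; ++i) {
    r[3 * i] = ref(i, 0); r[3 * i + 1] = ref(i, 1); r[3 * i + 2] = ref(i, 2);
  }
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nr; ++j) {
      double d = dist2(&r[3 * j], &q[3 * i]);
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// k nearest reference rows for every query row (cross-set, brute force).
// [[Rcpp::export]]
List cpp_cross_knn(NumericMatrix query, NumericMatrix ref, int k) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (k < 1 || k > nr) stop("k must be in [1, nrow(ref)]");
  std::vector<double> q(3 * nq), r(3 * nr);
  for (int i = 0; i < nq; ++i) {
    q[3 * i] = query(i, 0); q[3 * i + 1] = query(i, 1); q[3 * i + 2] = query(i, 2);
  }
  for (int i = 0; i < nr; ++i) {
    r[3 * i] = ref(i, 0); r[3 * i + 1] = ref(i, 1); r[3 * i + 2] = ref(i, 2);
  }
  IntegerMatrix idx(nq, k);
  NumericMatrix d2(nq, k);
  std::vector<std::pair<double, int> > cand(nr);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nr; ++j)
      cand[j] = std::make_pair(dist2(&r[3 * j], &q[3 * i]), j);
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int t = 0; t < k; ++t) { idx(i, t) = cand[t].second + 1; d2(i, t) = cand[t].first; }
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}

// Eigenvalues (descending) of a symmetric 3x3 matrix, analytic form.
static void eig3_sym(double a11, double a22, double a33,
                     double a12, double a13, double a23, double ev[3]) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 < 1e-30) {
    ev[0] = a11; ev[1] = a22; ev[2] = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
    double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    // det(B / p) / 2
    double c11 = b11 / p, c22 = b22 / p, c33 = b33 / p;
    double c12 = a12 / p, c13 = a13 / p, c23 = a23 / p;
    double detB = c11 * (c22 * c33 - c23 * c23)
                - c12 * (c12 * c33 - c23 * c13)
                + c13 * (c12 * c23 - c22 * c13);
    double r = detB / 2.0;
    r = std::max(-1.0, std::min(1.0, r));
    double phi = std::acos(r) / 3.0;
    ev[0] = q + 2.0 * p * std::cos(phi);
    ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    ev[1] = 3.0 * q - ev[0] - ev[2];
  }
  std::sort(ev, ev + 3, std::greater<double>());
}

// Per-point covariance eigenvalues over the radius neighbourhood (point
// included). Returns n x 3 eigenvalues (descending) and neighbour counts.
// [[Rcpp::export]]
List cpp_local_cov_eigs(NumericMatrix coords, double radius) {
  const int n = coords.nrow();
  if (radius <= 0) stop("radius must be positive");
  std::vector<double> pts(3 * n);
  for (int i = 0; i < n; ++i) {
    pts[3 * i] = coords(i, 0); pts[3 * i + 1] = coords(i, 1); pts[3 * i + 2] = coords(i, 2);
  }
  Grid g; g.build(pts, n, radius);
  NumericMatrix eigs(n, 3);
  IntegerVector counts(n);
  std::vector<std::pair<double, int> > hits;
  for (int i = 0; i < n; ++i) {
    g.query(&pts[3 * i], radius, hits);
    int m = hits.size();
    counts[i] = m - 1;  // neighbours excluding the point itself
    double mx = 0, my = 0, mz = 0;
    for (auto& h : hits) { mx += pts[3 * h.second]; my += pts[3 * h.second + 1]; mz += pts[3 * h.second + 2]; }
    mx /= m; my /= m; mz /= m;
    double sxx = 0, syy = 0, szz = 0, sxy = 0, sxz = 0, syz = 0;
    for (auto& h : hits) {
      double dx = pts[3 * h.second] - mx, dy = pts[3 * h.second + 1] - my, dz = pts[3 * h.second + 2] - mz;
      sxx += dx * dx; syy += dy * dy; szz += dz * dz;
      sxy += dx * dy; sxz += dx * dz; syz += dy * dz;
    }
    double ev[3];
    eig3_sym(sxx / m, syy / m, szz / m, sxy / m, sxz / m, syz / m, ev);
    eigs(i, 0) = ev[0]; eigs(i, 1) = ev[1]; eigs(i, 2) = ev[2];
  }
  return List::create(_["eigs"] = eigs, _["n_neighbors"] = counts);
}

// Indices (1-based) of all points within radius of each point, self excluded.
// [[Rcpp::export]]
List cpp_radius_neighbors(NumericMatrix coords, double radius) {
  const int n = coords.nrow();
  if (radius <= 0) stop("radius must be positive");
  std::vector<double> pts(3 * n);
  for (int i = 0; i < n; ++i) {
    pts[3 * i] = coords(i, 0); pts[3 * i + 1] = coords(i, 1); pts[3 * i + 2] = coords(i, 2);
  }
  Grid g; g.build(pts, n, radius);
  List out(n);
  std::vector<std::pair<double, int> > hits;
  for (int i = 0; i < n; ++i) {
    g.query(&pts[3 * i], radius, hits);
    std::sort(hits.begin(), hits.end());
    std::vector<int> ids;
    ids.reserve(hits.size());
    for (auto& h : hits) if (h.second != i) ids.push_back(h.second + 1);
    out[i] = wrap(ids);
  }
  return out;
}
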