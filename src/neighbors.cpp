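// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Uniform-grid spatial index over 3D points: cell key -> point indices.
namespace {

struct Grid {
  double cell;
  double ox, oy, oz;
  std::unordered_map<long long, std::vector<int> > cells;

  static long long key(int i, int j, int k) {
    // pack three 21-bit signed cell coordinates
    const long long B = 1 << 20;
    return ((i + B) << 42) | ((j + B) << 21) | (k + B);
  }

  void build(const NumericMatrix &P, double cell_size) {
    cell = cell_size;
    ox = oy = oz = R_PosInf;
    const int n = P.nrow();
    for (int i = 0; i < n; ++i) {
      if (P(i, 0) < ox) ox = P(i, 0);
      if (P(i, 1) < oy) oy = P(i, 1);
      if (P(i, 2) < oz) oz = P(i, 2);
    }
    cells.reserve(n);
    for (int i = 0; i < n; ++i) {
      cells[key(cx(P(i, 0)), cy(P(i, 1)), cz(P(i, 2)))].push_back(i);
    }
  }
  int cx(double x) const { return (int)std::floor((x - ox) / cell); }
  int cy(double y) const { return (int)std::floor((y - oy) / cell); }
  int cz(double z) const { return (int)std::floor((z - oz) / cell); }
};

inline double sqdist(const NumericMatrix &P, int i, int j) {
  const double dx = P(i, 0) - P(j, 0);
  const double dy = P(i, 1) - P(j, 1);
  const double dz = P(i, 2) - P(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

}  // namespace

// Mean distance from each point to its k nearest neighbours (self excluded),
// the statistic behind Statistical Outlier Removal. Expanding-shell search on
// a uniform grid; exact.
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix P, int k) {
  const int n = P.nrow();
  NumericVector out(n);
  if (n <= 1) return out;
  if (k > n - 1) k = n - 1;

  // cell size ~ expected kNN radius for a uniform density
  double xr[3];
  for (int c = 0; c < 3; ++c) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (P(i, c) < lo) lo = P(i, c);
      if (P(i, c) > hi) hi = P(i, c);
    }
    xr[c] = std::max(hi - lo, 1e-9);
  }
  double cell = std::cbrt(xr[0] * xr[1] * xr[2] * (double)(k + 1) / n);
  if (!std::isfinite(cell) || cell <= 0) cell = 1.0;
  Grid g;
  g.build(P, cell);

  std::vector<double> d2;
  for (int i = 0; i < n; ++i) {
    const int ci = g.cx(P(i, 0)), cj = g.cy(P(i, 1)), ck = g.cz(P(i, 2));
    d2.clear();
    int shell = 0;
    double kth = R_PosInf;
    while (true) {
      // collect candidates on the surface of the current Chebyshev shell
      for (int a = ci - shell; a <= ci + shell; ++a)
        for (int b = cj - shell; b <= cj + shell; ++b)
          for (int c = ck - shell; c <= ck + shell; ++c) {
            if (shell > 0 && std::abs(a - ci) != shell &&
                std::abs(b - cj) != shell && std::abs(c - ck) != shell)
              continue;
            auto it = g.cells.find(Grid::key(a, b, c));
            if (it == g.cells.end()) continue;
            for (int idx : it->second)
              if (idx != i) d2.push_back(sqdist(P, i, idx));
          }
      if ((int)d2.size() >= k) {
        std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
        kth = d2[k - 1];
        // all points within radius shell*cell of the query cell are covered
        const double covered = (double)shell * cell;
        if (kth <= covered * covered) break;
      }
      ++shell;
      if (shell > 2000) break;  // degenerate fallback, never hit in practice
    }
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
    std::sort(d2.begin(), d2.begin() + k);
    double s = 0;
    for (int m = 0; m < k; ++m) s += std::sqrt(d2[m]);
    out[i] = s / k;
  }
  return out;
}

// Per-point covariance eigen-decomposition over a spherical neighbourhood of
// the given radius (self included). Returns an n x 10 matrix:
// [l1 l2 l3 (descending eigenvalues), e_max (3), e_min (3), count].
// Rows with fewer than 3 neighbours get NA eigen entries.
// [[Rcpp::export]]
NumericMatrix cpp_local_eigen(NumericMatrix P, double radius) {
  const int n = P.nrow();
  NumericMatrix out(n, 10);
  Grid g;
  g.build(P, radius);
  const double r2 = radius * radius;

  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    const int ci = g.cx(P(i, 0)), cj = g.cy(P(i, 1)), ck = g.cz(P(i, 2));
    for (int a = ci - 1; a <= ci + 1; ++a)
      for (int b = cj - 1; b <= cj + 1; ++b)
        for (int c = ck - 1; c <= ck + 1; ++c) {
          auto it = g.cells.find(Grid::key(a, b, c));
          if (it == g.cells.end()) continue;
          for (int idx : it->second)
            if (sqdist(P, i, idx) <= r2) nb.push_back(idx);
        }
    const int m = (int)nb.size();
    out(i, 9) = m;
    if (m < 3) {
      for (int c = 0; c < 9; ++c) out(i, c) = NA_REAL;
      continue;
    }
    arma::vec mu(3, arma::fill::zeros);
    for (int idx : nb) {
      mu[0] += P(idx, 0); mu[1] += P(idx, 1); mu[2] += P(idx, 2);
    }
    mu /= m;
    arma::mat C(3, 3, arma::fill::zeros);
    for (int idx : nb) {
      arma::vec d = {P(idx, 0) - mu[0], P(idx, 1) - mu[1], P(idx, 2) - mu[2]};
      C += d * d.t();
    }
    C /= m;
    arma::vec eval;
    arma::mat evec;
    if (!arma::eig_sym(eval, evec, C)) {
      for (int c = 0; c < 9; ++c) out(i, c) = NA_REAL;
      continue;
    }
    // arma returns ascending; report descending
    out(i, 0) = eval[2]; out(i, 1) = eval[1]; out(i, 2) = eval[0];
    for (int c = 0; c < 3; ++c) {
      out(i, 3 + c) = evec(c, 2);  // principal direction
      out(i, 6 + c) = evec(c, 0);  // normal direction
    }
  }
  return out;
}
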