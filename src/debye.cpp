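#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static inline double sinc(double x) {
  // sin(x)/x, stable near 0
  if (std::fabs(x) < 1e-8) return 1.0 - x * x / 6.0;
  return std::sin(x) / x;
}

// Exact Debye double loop: I(s) = sum_i f_i^2 + 2 sum_{i<j} f_i f_j sinc(s r_ij)
// [[Rcpp::export]]
NumericVector cpp_debye_exact(NumericMatrix xyz, NumericVector f,
                              NumericVector s) {
  const int n = xyz.nrow(), ns = s.size();
  NumericVector I(ns);
  double self = 0.0;
  for (int i = 0; i < n; ++i) self += f[i] * f[i];
  for (int k = 0; k < ns; ++k) I[k] = self;
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2), fi = f[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1),
                   dz = zi - xyz(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double w = 2.0 * fi * f[j];
      for (int k = 0; k < ns; ++k) I[k] += w * sinc(s[k] * r);
    }
  }
  return I;
}

// Weighted pair-distance histogram with fixed bin width; returns bin centres
// and summed pair weights (2 f_i f_j per i<j pair), plus the self term.
// [[Rcpp::export]]
List cpp_pair_hist(NumericMatrix xyz, NumericVector f, double bin_width) {
  const int n = xyz.nrow();
  double self = 0.0, rmax = 0.0;
  for (int i = 0; i < n; ++i) self += f[i] * f[i];
  // first pass: max distance (cheap relative to second pass)
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = xyz(i, 0); y[i] = xyz(i, 1); z[i] = xyz(i, 2);
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > rmax) rmax = r2;
    }
  rmax = std::sqrt(rmax);
  const int nbin = std::max(1, (int)std::ceil(rmax / bin_width) + 1);
  NumericVector w(nbin);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)(r / bin_width);
      if (b >= nbin) b = nbin - 1;
      w[b] += 2.0 * f[i] * f[j];
    }
  NumericVector centres(nbin);
  for (int b = 0; b < nbin; ++b) centres[b] = (b + 0.5) * bin_width;
  return List::create(_["r"] = centres, _["w"] = w, _["self"] = self);
}

// I(s) from a precomputed pair histogram
// [[Rcpp::export]]
NumericVector cpp_debye_from_hist(NumericVector r, NumericVector w,
                                  double self, NumericVector s) {
  const int nb = r.size(), ns = s.size();
  NumericVector I(ns);
  for (int k = 0; k < ns; ++k) {
    double acc = self;
    const double sk = s[k];
    for (int b = 0; b < nb; ++b)
      if (w[b] != 0.0) acc += w[b] * sinc(sk * r[b]);
    I[k] = acc;
  }
  return I;
}

// Count van der Waals clashes with a cell list. A pair (i, j) clashes when
// radii[i] + radii[j] - d_ij > cutoff. Pairs sharing a positive group id are
// exempt (same rigid body); pairs sharing a non-positive group id (one
// flexible chain) are exempt when they are sequence neighbours (|i-j| <= 2).
// [[Rcpp::export]]
int cpp_clash_count(NumericMatrix xyz, NumericVector radii,
                    IntegerVector group, double cutoff) {
  const int n = xyz.nrow();
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  const double cell = std::max(2.0 * rmax, 1.0);
  std::unordered_map<long long, std::vector<int> > cells;
  std::vector<long long> key(n);
  for (int i = 0; i < n; ++i) {
    long long cx = (long long)std::floor(xyz(i, 0) / cell);
    long long cy = (long long)std::floor(xyz(i, 1) / cell);
    long long cz = (long long)std::floor(xyz(i, 2) / cell);
    long long k = ((cx + 1048576) << 42) | ((cy + 1048576) << 21) |
                  (cz + 1048576);
    key[i] = k;
    cells[k].push_back(i);
  }
  int count = 0;
  for (int i = 0; i < n; ++i) {
    long long cx = (long long)std::floor(xyz(i, 0) / cell);
    long long cy = (long long)std::floor(xyz(i, 1) / cell);
    long long cz = (long long)std::floor(xyz(i, 2) / cell);
    for (long long ax = cx - 1; ax <= cx + 1; ++ax)
      for (long long ay = cy - 1; ay <= cy + 1; ++ay)
        for (long long az = cz - 1; az <= cz + 1; ++az) {
          long long k = ((ax + 1048576) << 42) | ((ay + 1048576) << 21) |
                        (az + 1048576);
          std::unordered_map<long long, std::vector<int> >::const_iterator
              it = cells.find(k);
          if (it == cells.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t m = 0; m < v.size(); ++m) {
            const int j = v[m];
            if (j <= i) continue;
            if (group[i] == group[j]) {
              if (group[i] > 0) continue;                 // same rigid body
              if (std::abs(i - j) <= 2) continue;         // bonded chain
            }
            const double dx = xyz(i, 0) - xyz(j, 0),
                         dy = xyz(i, 1) - xyz(j, 1),
                         dz = xyz(i, 2) - xyz(j, 2);
            const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (radii[i] + radii[j] - d > cutoff) ++count;
          }
        }
  }
  return count;
}

// Cross term of the Debye sum between two scatterer sets:
// sum_{i in A} sum_{j in B} 2 f_i f_j sinc(s r_ij)
// [[Rcpp::export]]
NumericVector cpp_debye_cross(NumericMatrix xyzA, NumericVector fA,
                              NumericMatrix xyzB, NumericVector fB,
                              NumericVector s) {
  const int na = xyzA.nrow(), nb = xyzB.nrow(), ns = s.size();
  NumericVector I(ns);
  for (int i = 0; i < na; ++i) {
    const double xi = xyzA(i, 0), yi = xyzA(i, 1), zi = xyzA(i, 2),
                 fi = fA[i];
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - xyzB(j, 0), dy = yi - xyzB(j, 1),
                   dz = zi - xyzB(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double w = 2.0 * fi * fB[j];
      for (int k = 0; k < ns; ++k) I[k] += w * sinc(s[k] * r);
    }
  }
  return I;
}
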