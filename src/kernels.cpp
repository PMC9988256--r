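#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-row quantile (type-7 linear interpolation) of a numeric matrix.
// Used for the elementwise consensus across per-individual TOMs, where the
// number of rows (gene pairs) is in the millions and apply() would be slow.
// [[Rcpp::export]]
NumericVector row_quantile_cpp(NumericMatrix x, double q) {
  int n = x.nrow(), p = x.ncol();
  NumericVector out(n);
  std::vector<double> row(p);
  double h = (p - 1) * q;
  int lo = (int)std::floor(h);
  int hi = lo + 1 < p ? lo + 1 : lo;
  double g = h - lo;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = x(i, j);
    std::sort(row.begin(), row.end());
    out[i] = (1.0 - g) * row[lo] + g * row[hi];
  }
  return out;
}

// Mean-shift in d dimensions with grid seeding (bin size = bandwidth).
// Seeds are the means of occupied bins; each seed climbs to a local density
// mode by iterated kernel-weighted averaging (Gaussian kernel truncated at
// 3 bandwidths by default, or a flat kernel over the bandwidth ball); modes
// closer than merge_radius are merged (largest support wins); every point
// is assigned to the nearest surviving mode.
// Deterministic: bins are traversed in sorted key order.
// [[Rcpp::export]]
List mean_shift_cpp(NumericMatrix pts, double bandwidth, double merge_radius,
                    bool gaussian = true, int max_iter = 300,
                    double tol_frac = 1e-4) {
  int n = pts.nrow(), d = pts.ncol();
  double h2 = bandwidth * bandwidth;
  double cut2 = gaussian ? 9.0 * h2 : h2;
  double tol2 = (tol_frac * bandwidth) * (tol_frac * bandwidth);

  // grid seeding
  std::map<std::vector<long long>, std::pair<std::vector<double>, int> > bins;
  for (int i = 0; i < n; ++i) {
    std::vector<long long> key(d);
    for (int j = 0; j < d; ++j)
      key[j] = (long long)std::floor(pts(i, j) / bandwidth);
    auto it = bins.find(key);
    if (it == bins.end()) {
      std::vector<double> s(d);
      for (int j = 0; j < d; ++j) s[j] = pts(i, j);
      bins[key] = std::make_pair(s, 1);
    } else {
      for (int j = 0; j < d; ++j) it->second.first[j] += pts(i, j);
      it->second.second += 1;
    }
  }

  int nseed = bins.size();
  std::vector<std::vector<double> > modes;
  std::vector<int> support;
  modes.reserve(nseed);

  for (auto &kv : bins) {
    std::vector<double> m(d);
    for (int j = 0; j < d; ++j) m[j] = kv.second.first[j] / kv.second.second;
    int cnt = 0;
    for (int it = 0; it < max_iter; ++it) {
      std::vector<double> s(d, 0.0);
      double wsum = 0.0;
      cnt = 0;
      for (int i = 0; i < n; ++i) {
        double dist2 = 0.0;
        for (int j = 0; j < d; ++j) {
          double diff = pts(i, j) - m[j];
          dist2 += diff * diff;
        }
        if (dist2 <= cut2) {
          double w = gaussian ? std::exp(-0.5 * dist2 / h2) : 1.0;
          for (int j = 0; j < d; ++j) s[j] += w * pts(i, j);
          wsum += w;
          ++cnt;
        }
      }
      if (cnt == 0) break; // isolated seed: stay put
      double shift2 = 0.0;
      for (int j = 0; j < d; ++j) {
        double nj = s[j] / wsum;
        double diff = nj - m[j];
        shift2 += diff * diff;
        m[j] = nj;
      }
      if (shift2 < tol2) break;
    }
    modes.push_back(m);
    support.push_back(cnt > 0 ? cnt : 1);
  }

  // merge modes within merge_radius, largest support first
  std::vector<int> order(modes.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return support[a] > support[b]; });
  double mr2 = merge_radius * merge_radius;
  std::vector<std::vector<double> > kept;
  for (int idx : order) {
    bool absorbed = false;
    for (auto &k : kept) {
      double dist2 = 0.0;
      for (int j = 0; j < d; ++j) {
        double diff = modes[idx][j] - k[j];
        dist2 += diff * diff;
      }
      if (dist2 <= mr2) { absorbed = true; break; }
    }
    if (!absorbed) kept.push_back(modes[idx]);
  }

  // assign points to nearest mode
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bi = 0;
    for (size_t k = 0; k < kept.size(); ++k) {
      double dist2 = 0.0;
      for (int j = 0; j < d; ++j) {
        double diff = pts(i, j) - kept[k][j];
        dist2 += diff * diff;
      }
      if (dist2 < best) { best = dist2; bi = k; }
    }
    labels[i] = bi + 1;
  }

  NumericMatrix centers(kept.size(), d);
  for (size_t k = 0; k < kept.size(); ++k)
    for (int j = 0; j < d; ++j) centers(k, j) = kept[k][j];

  return List::create(_["labels"] = labels, _["centers"] = centers);
}
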