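#include <Rcpp.h>
using namespace Rcpp;

// Classical k-medoids (PAM): greedy BUILD seeding followed by SWAP local
// search. Euclidean distance on the embedding coordinates, computed on the
// fly (no n x n matrix is materialized, so large gene sets fit in memory).
// Deterministic: all ties are broken by the lowest point index.

static inline double dist_pt(const NumericMatrix& X, int a, int b) {
  double s = 0.0;
  for (int d = 0; d < X.ncol(); ++d) {
    double t = X(a, d) - X(b, d);
    s += t * t;
  }
  return std::sqrt(s);
}

static void dist_col(const NumericMatrix& X, int h, std::vector<double>& out) {
  const int n = X.nrow();
  for (int j = 0; j < n; ++j) out[j] = dist_pt(X, j, h);
}

// [[Rcpp::export]]
List pam_cpp(NumericMatrix X, int k, int max_iter = 200) {
  const int n = X.nrow();
  std::vector<int> medoids;
  medoids.reserve(k);
  std::vector<bool> is_medoid(n, false);
  std::vector<double> dnear(n, R_PosInf), dsec(n, R_PosInf);
  std::vector<int> near_idx(n, -1);
  std::vector<double> col(n);

  // BUILD: first medoid minimizes total distance to all points
  {
    double best = R_PosInf;
    int best_h = -1;
    for (int h = 0; h < n; ++h) {
      dist_col(X, h, col);
      double tot = 0.0;
      for (int j = 0; j < n; ++j) tot += col[j];
      if (tot < best - 1e-12) { best = tot; best_h = h; }
    }
    medoids.push_back(best_h);
    is_medoid[best_h] = true;
    dist_col(X, best_h, col);
    for (int j = 0; j < n; ++j) { dnear[j] = col[j]; near_idx[j] = best_h; }
  }
  // subsequent medoids: maximize the decrease in total cost
  while ((int)medoids.size() < k) {
    double best_gain = -1.0;
    int best_h = -1;
    for (int h = 0; h < n; ++h) {
      if (is_medoid[h]) continue;
      dist_col(X, h, col);
      double gain = 0.0;
      for (int j = 0; j < n; ++j) {
        double g = dnear[j] - col[j];
        if (g > 0.0) gain += g;
      }
      if (gain > best_gain + 1e-12) { best_gain = gain; best_h = h; }
    }
    medoids.push_back(best_h);
    is_medoid[best_h] = true;
    dist_col(X, best_h, col);
    for (int j = 0; j < n; ++j) {
      if (col[j] < dnear[j]) { dnear[j] = col[j]; near_idx[j] = best_h; }
    }
  }

  // refresh nearest and second-nearest medoid distances
  auto refresh = [&]() {
    for (int j = 0; j < n; ++j) {
      double d1 = R_PosInf, d2 = R_PosInf;
      int i1 = -1;
      for (int m : medoids) {
        double d = dist_pt(X, j, m);
        if (d < d1 - 1e-15 || (std::fabs(d - d1) <= 1e-15 && m < i1)) {
          d2 = d1; d1 = d; i1 = m;
        } else if (d < d2) {
          d2 = d;
        }
      }
      dnear[j] = d1; dsec[j] = d2; near_idx[j] = i1;
    }
  };
  refresh();

  double build_cost = 0.0;
  for (int j = 0; j < n; ++j) build_cost += dnear[j];

  // SWAP: accept the best strictly-improving medoid/non-medoid exchange
  int iter = 0;
  if (k < n) {
    while (iter < max_iter) {
      ++iter;
      double best_delta = -1e-10;
      int best_m = -1, best_h = -1;
      for (int h = 0; h < n; ++h) {
        if (is_medoid[h]) continue;
        dist_col(X, h, col);
        for (size_t mi = 0; mi < medoids.size(); ++mi) {
          int m = medoids[mi];
          double delta = 0.0;
          for (int j = 0; j < n; ++j) {
            if (near_idx[j] == m) {
              double alt = std::min(col[j], dsec[j]);
              delta += alt - dnear[j];
            } else if (col[j] < dnear[j]) {
              delta += col[j] - dnear[j];
            }
          }
          if (delta < best_delta - 1e-12) {
            best_delta = delta; best_m = m; best_h = h;
          }
        }
      }
      if (best_h < 0) break;
      is_medoid[best_m] = false;
      is_medoid[best_h] = true;
      for (size_t mi = 0; mi < medoids.size(); ++mi)
        if (medoids[mi] == best_m) medoids[mi] = best_h;
      refresh();
    }
  }

  double total_cost = 0.0;
  for (int j = 0; j < n; ++j) total_cost += dnear[j];

  IntegerVector med_out(k), labels(n);
  std::vector<int> sorted_meds(medoids);
  std::sort(sorted_meds.begin(), sorted_meds.end());
  for (int i = 0; i < k; ++i) med_out[i] = sorted_meds[i] + 1;  // 1-based
  for (int j = 0; j < n; ++j) {
    // label = rank of the assigned medoid among sorted medoid indices
    int m = near_idx[j];
    int lab = std::lower_bound(sorted_meds.begin(), sorted_meds.end(), m) -
              sorted_meds.begin();
    labels[j] = lab + 1;
  }

  return List::create(_["medoids"] = med_out, _["labels"] = labels,
                      _["total_cost"] = total_cost,
                      _["build_cost"] = build_cost,
                      _["swap_iterations"] = iter);
}
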