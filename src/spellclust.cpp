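#include <Rcpp.h>
using namespace Rcpp;

// Mixed-data dissimilarity with pairwise-deletion weighting.
// kinds: 0 = quantitative (variance-standardised squared difference),
//        1 = categorical (simple mismatch).
// d(i,j)^2 = sum_k delta_ijk w_k g_k / sum_k delta_ijk w_k over variables
// observed in both subjects; a pair sharing no observed variable is an error.

static inline double pair_d2(const NumericMatrix& X, const NumericMatrix& Y,
                             int i, int j,
                             const IntegerVector& kinds,
                             const NumericVector& w,
                             const NumericVector& s,
                             bool& ok) {
  const int p = X.ncol();
  double num = 0.0, den = 0.0;
  for (int k = 0; k < p; ++k) {
    if (w[k] <= 0.0) continue;
    double xi = X(i, k), yj = Y(j, k);
    if (NumericVector::is_na(xi) || NumericVector::is_na(yj)) continue;
    double g;
    if (kinds[k] == 0) {
      double z = (xi - yj) / s[k];
      g = z * z;
    } else {
      g = (xi != yj) ? 1.0 : 0.0;
    }
    num += w[k] * g;
    den += w[k];
  }
  if (den <= 0.0) { ok = false; return NA_REAL; }
  ok = true;
  return num / den;
}

// [[Rcpp::export]]
NumericMatrix cpp_mixed_distance(NumericMatrix X, IntegerVector kinds,
                                 NumericVector w, NumericVector s) {
  const int n = X.nrow();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    D(i, i) = 0.0;
    for (int j = i + 1; j < n; ++j) {
      bool ok;
      double d2 = pair_d2(X, X, i, j, kinds, w, s, ok);
      if (!ok)
        stop("no comparable variables for subject pair (%d, %d)", i + 1, j + 1);
      double d = std::sqrt(d2);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// [[Rcpp::export]]
NumericMatrix cpp_cross_distance(NumericMatrix X, NumericMatrix Y,
                                 IntegerVector kinds,
                                 NumericVector w, NumericVector s) {
  const int n = X.nrow(), m = Y.nrow();
  NumericMatrix D(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      bool ok;
      double d2 = pair_d2(X, Y, i, j, kinds, w, s, ok);
      if (!ok)
        stop("no comparable variables for item pair (%d, %d)", i + 1, j + 1);
      D(i, j) = std::sqrt(d2);
    }
  }
  return D;
}

// Deterministic PAM: BUILD greedy initialisation followed by steepest-descent
// SWAP. All ties broken by lowest index (strict comparisons while scanning in
// ascending order). Returns the cost after BUILD and after every accepted
// swap so callers can assert monotone descent.

// [[Rcpp::export]]
List cpp_pam(NumericMatrix D, int k) {
  const int n = D.nrow();
  if (k < 1 || k > n) stop("k must be between 1 and n");

  std::vector<int> medoids;
  medoids.reserve(k);
  std::vector<bool> is_medoid(n, false);

  // BUILD: first medoid minimises total distance.
  {
    int best = 0;
    double best_cost = R_PosInf;
    for (int j = 0; j < n; ++j) {
      double c = 0.0;
      for (int i = 0; i < n; ++i) c += D(i, j);
      if (c < best_cost) { best_cost = c; best = j; }
    }
    medoids.push_back(best);
    is_medoid[best] = true;
  }
  std::vector<double> dn(n);  // distance to nearest medoid
  for (int i = 0; i < n; ++i) dn[i] = D(i, medoids[0]);

  while ((int)medoids.size() < k) {
    int best = -1;
    double best_gain = -1.0;
    for (int j = 0; j < n; ++j) {
      if (is_medoid[j]) continue;
      double gain = 0.0;
      for (int i = 0; i < n; ++i) {
        double diff = dn[i] - D(i, j);
        if (diff > 0.0) gain += diff;
      }
      if (gain > best_gain) { best_gain = gain; best = j; }
    }
    medoids.push_back(best);
    is_medoid[best] = true;
    for (int i = 0; i < n; ++i)
      if (D(i, best) < dn[i]) dn[i] = D(i, best);
  }

  std::sort(medoids.begin(), medoids.end());

  // nearest / second-nearest bookkeeping (nearest ties -> lowest medoid index,
  // guaranteed by scanning medoids in ascending order with strict <).
  std::vector<int> nearest(n);
  std::vector<double> ds(n);
  auto refresh = [&]() {
    for (int i = 0; i < n; ++i) {
      double d1 = R_PosInf, d2 = R_PosInf;
      int m1 = -1;
      for (size_t a = 0; a < medoids.size(); ++a) {
        double d = D(i, medoids[a]);
        if (d < d1) { d2 = d1; d1 = d; m1 = medoids[a]; }
        else if (d < d2) { d2 = d; }
      }
      dn[i] = d1; ds[i] = d2; nearest[i] = m1;
    }
  };
  refresh();

  auto total_cost = [&]() {
    double c = 0.0;
    for (int i = 0; i < n; ++i) c += dn[i];
    return c;
  };

  std::vector<double> trace;
  trace.push_back(total_cost());

  if (k < n && k >= 1) {
    const double eps = 1e-12;
    for (;;) {
      double best_delta = -eps;
      int best_m = -1, best_h = -1;
      for (size_t a = 0; a < medoids.size(); ++a) {
        int m = medoids[a];
        for (int h = 0; h < n; ++h) {
          if (is_medoid[h]) continue;
          double delta = 0.0;
          for (int i = 0; i < n; ++i) {
            double dih = D(i, h);
            if (nearest[i] == m) {
              double nd = std::min(ds[i], dih);
              delta += nd - dn[i];
            } else if (dih < dn[i]) {
              delta += dih - dn[i];
            }
          }
          if (delta < best_delta) { best_delta = delta; best_m = m; best_h = h; }
        }
      }
      if (best_m < 0) break;
      is_medoid[best_m] = false;
      is_medoid[best_h] = true;
      for (size_t a = 0; a < medoids.size(); ++a)
        if (medoids[a] == best_m) medoids[a] = best_h;
      std::sort(medoids.begin(), medoids.end());
      refresh();
      trace.push_back(total_cost());
    }
  }

  // Final assignment: cluster labels 1..k in medoid-index order.
  IntegerVector assignment(n);
  for (int i = 0; i < n; ++i) {
    double d1 = R_PosInf;
    int lab = -1;
    for (size_t a = 0; a < medoids.size(); ++a) {
      double d = D(i, medoids[a]);
      if (d < d1) { d1 = d; lab = (int)a + 1; }
    }
    assignment[i] = lab;
    dn[i] = d1;
  }

  IntegerVector med_out(k);
  for (int a = 0; a < k; ++a) med_out[a] = medoids[a] + 1;

  return List::create(_["medoids"] = med_out,
                      _["assignment"] = assignment,
                      _["cost"] = total_cost(),
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
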