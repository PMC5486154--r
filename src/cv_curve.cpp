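#include <Rcpp.h>
using namespace Rcpp;

// Pooled cross-validated accuracy of a Gaussian naive Bayes classifier as a
// function of the number of top-ranked features ("add one feature in").
//
// X         : n x p feature matrix
// y         : length-n 0/1 labels
// ranking   : p feature indices (1-based), descending relevance
// sub_idx   : ns x R matrix of 1-based row indices into X, one class-balanced
//             subsample per repetition column
// fold_id   : ns x R matrix of fold labels (1..K) aligned with sub_idx
// n_folds   : K
//
// Returns accuracy[d], d = 1..p: correct predictions pooled over all
// repetitions and folds divided by total predictions. Mirrors gnb_fit():
// population-variance moments, variance floor 1e-9 * max overall training
// feature variance, log-space posteriors, ties to class 0.
// [[Rcpp::export]]
NumericVector cpp_cv_curve(NumericMatrix X, IntegerVector y,
                           IntegerVector ranking, IntegerMatrix sub_idx,
                           IntegerMatrix fold_id, int n_folds) {
  const int p = X.ncol();
  const int ns = sub_idx.nrow();
  const int R = sub_idx.ncol();

  std::vector<double> correct(p, 0.0), total(p, 0.0);
  std::vector<double> sum0(p), ss0(p), sum1(p), ss1(p);
  std::vector<double> mu0(p), v0(p), mu1(p), v1(p);

  for (int r = 0; r < R; ++r) {
    for (int f = 1; f <= n_folds; ++f) {
      int n0 = 0, n1 = 0;
      std::fill(sum0.begin(), sum0.end(), 0.0);
      std::fill(ss0.begin(), ss0.end(), 0.0);
      std::fill(sum1.begin(), sum1.end(), 0.0);
      std::fill(ss1.begin(), ss1.end(), 0.0);

      for (int i = 0; i < ns; ++i) {
        if (fold_id(i, r) == f) continue;  // test row
        const int row = sub_idx(i, r) - 1;
        if (y[sub_idx(i, r) - 1] == 0) {
          ++n0;
          for (int j = 0; j < p; ++j) {
            const double v = X(row, j);
            sum0[j] += v; ss0[j] += v * v;
          }
        } else {
          ++n1;
          for (int j = 0; j < p; ++j) {
            const double v = X(row, j);
            sum1[j] += v; ss1[j] += v * v;
          }
        }
      }
      if (n0 == 0 || n1 == 0) continue;  // degenerate training fold

      const int nt = n0 + n1;
      double max_var = 0.0;
      for (int j = 0; j < p; ++j) {
        mu0[j] = sum0[j] / n0;
        v0[j] = ss0[j] / n0 - mu0[j] * mu0[j];
        mu1[j] = sum1[j] / n1;
        v1[j] = ss1[j] / n1 - mu1[j] * mu1[j];
        const double s = sum0[j] + sum1[j];
        const double m = s / nt;
        const double ov = (ss0[j] + ss1[j]) / nt - m * m;
        if (ov > max_var) max_var = ov;
      }
      double floor_ = 1e-9 * max_var;
      if (floor_ <= 0.0) floor_ = 1e-12;
      for (int j = 0; j < p; ++j) {
        if (v0[j] < floor_) v0[j] = floor_;
        if (v1[j] < floor_) v1[j] = floor_;
      }
      const double lp0 = std::log((double)n0 / nt);
      const double lp1 = std::log((double)n1 / nt);

      for (int i = 0; i < ns; ++i) {
        if (fold_id(i, r) != f) continue;
        const int row = sub_idx(i, r) - 1;
        const int truth = y[row];
        double ll0 = lp0, ll1 = lp1;
        for (int dj = 0; dj < p; ++dj) {
          const int j = ranking[dj] - 1;
          const double x = X(row, j);
          const double d0 = x - mu0[j];
          const double d1 = x - mu1[j];
          ll0 += -0.5 * std::log(2.0 * M_PI * v0[j]) - d0 * d0 / (2.0 * v0[j]);
          ll1 += -0.5 * std::log(2.0 * M_PI * v1[j]) - d1 * d1 / (2.0 * v1[j]);
          const int pred = (ll1 > ll0) ? 1 : 0;  // tie -> class 0
          if (pred == truth) correct[dj] += 1.0;
          total[dj] += 1.0;
        }
      }
    }
  }

  NumericVector acc(p);
  for (int d = 0; d < p; ++d) {
    acc[d] = total[d] > 0.0 ? correct[d] / total[d] : NA_REAL;
  }
  return acc;
}
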