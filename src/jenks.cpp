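#include <Rcpp.h>
using namespace Rcpp;

// Fisher's exact dynamic program for optimal 1-D classification of sorted,
// weighted values into k classes minimizing total within-class weighted sum
// of squared deviations. Among equal-cost partitions the smallest feasible
// first break (and recursively the smallest subsequent breaks) is chosen by
// scanning candidate split points from the left and accepting strict
// improvements only.
//
// x: sorted unique values; w: positive weights (multiplicities).
// Returns the 1-based index of the last element of each of the first k-1
// classes (the break positions).
// [[Rcpp::export]]
IntegerVector jenks_dp(NumericVector x, NumericVector w, int k) {
  int n = x.size();
  if (k < 1 || k > n) stop("k must lie in 1..n");
  std::vector<double> cw(n + 1, 0.0), cwx(n + 1, 0.0), cwx2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cw[i + 1] = cw[i] + w[i];
    cwx[i + 1] = cwx[i] + w[i] * x[i];
    cwx2[i + 1] = cwx2[i] + w[i] * x[i] * x[i];
  }
  // ssd of elements (i..j] in cumulative indexing (0-based i < j <= n)
  auto ssd = [&](int i, int j) {
    double W = cw[j] - cw[i];
    double S = cwx[j] - cwx[i];
    double S2 = cwx2[j] - cwx2[i];
    double v = S2 - S * S / W;
    return v > 0 ? v : 0.0;
  };
  const double INF = std::numeric_limits<double>::infinity();
  // scost[c][i]: best cost of splitting elements (i..n] into c classes;
  // back[c][i]: end of the first of those classes — scanning candidate ends
  // in ascending order and accepting strict improvements only makes the
  // reconstructed break sequence lexicographically smallest (smallest first
  // break among equal-cost partitions).
  std::vector<std::vector<double>> scost(k + 1, std::vector<double>(n + 1, INF));
  std::vector<std::vector<int>> back(k + 1, std::vector<int>(n + 1, -1));
  for (int i = 0; i < n; ++i) scost[1][i] = ssd(i, n);
  for (int c = 2; c <= k; ++c) {
    for (int i = 0; i + c <= n; ++i) {
      double best = INF; int arg = -1;
      for (int j = i + 1; j + (c - 1) <= n; ++j) {  // first class is (i..j]
        double v = ssd(i, j) + scost[c - 1][j];
        if (arg < 0 || v < best - 1e-12 * (1.0 + std::fabs(best))) {
          best = v; arg = j;
        }
      }
      scost[c][i] = best;
      back[c][i] = arg;
    }
  }
  IntegerVector breaks(k - 1);
  int i = 0;
  for (int c = k; c >= 2; --c) {
    i = back[c][i];
    breaks[k - c] = i;  // 1-based index of the last element of each class
  }
  return breaks;
}

// Per-cell slope of an ordinary least-squares line through
// (1, y1), ..., (n, yn) for every row of Y (cells x epochs).
// [[Rcpp::export]]
NumericVector ols_slopes(NumericMatrix Y) {
  int ncell = Y.nrow(), n = Y.ncol();
  double sx = 0, sxx = 0;
  for (int i = 1; i <= n; ++i) { sx += i; sxx += (double)i * i; }
  double denom = n * sxx - sx * sx;
  NumericVector K(ncell);
  for (int c = 0; c < ncell; ++c) {
    double sy = 0, sxy = 0;
    for (int i = 0; i < n; ++i) {
      sy += Y(c, i);
      sxy += (i + 1.0) * Y(c, i);
    }
    K[c] = (n * sxy - sx * sy) / denom;
  }
  return K;
}
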