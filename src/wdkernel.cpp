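#include <Rcpp.h>
using namespace Rcpp;

// Weighted degree string kernel between rows i of X and j of Y, both coded as
// integer residue matrices with L columns.  Uses the match-run identity: a
// maximal run of m consecutive positional matches contributes
// sum_{p <= min(m,d)} beta_p * (m - p + 1), which equals the naive
// substring-enumeration sum but costs O(L) per pair.
static double pair_kernel(const IntegerMatrix& X, const IntegerMatrix& Y,
                          int i, int j, const NumericVector& beta) {
  const int L = X.ncol();
  const int d = beta.size();
  double k = 0.0;
  int run = 0;
  for (int l = 0; l <= L; ++l) {
    bool match = (l < L) && (X(i, l) == Y(j, l));
    if (match) {
      ++run;
    } else if (run > 0) {
      const int pmax = run < d ? run : d;
      for (int p = 1; p <= pmax; ++p) k += beta[p - 1] * (run - p + 1);
      run = 0;
    }
  }
  return k;
}

// [[Rcpp::export]]
NumericMatrix cpp_gram(IntegerMatrix X, NumericVector beta) {
  const int n = X.nrow();
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double v = pair_kernel(X, X, i, j, beta);
      K(i, j) = v;
      K(j, i) = v;
    }
  return K;
}

// [[Rcpp::export]]
NumericMatrix cpp_cross_gram(IntegerMatrix X, IntegerMatrix Y,
                             NumericVector beta) {
  const int n = X.nrow(), m = Y.nrow();
  NumericMatrix K(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) K(i, j) = pair_kernel(X, Y, i, j, beta);
  return K;
}

// Per-length match-window counts: out[i, j, p-1] = number of positions l such
// that the length-p substrings of peptides i and j starting at l are equal.
// Any degree-d Gram is then a beta-weighted sum over the third axis, which
// makes hyperparameter grids over d nearly free.
// [[Rcpp::export]]
NumericVector cpp_match_count_array(IntegerMatrix X) {
  const int n = X.nrow(), L = X.ncol();
  NumericVector out(static_cast<R_xlen_t>(n) * n * L);
  const R_xlen_t nn = static_cast<R_xlen_t>(n) * n;
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      int run = 0;
      for (int l = 0; l <= L; ++l) {
        bool match = (l < L) && (X(i, l) == X(j, l));
        if (match) {
          ++run;
        } else if (run > 0) {
          for (int p = 1; p <= run; ++p) {
            double c = run - p + 1;
            out[nn * (p - 1) + n * j + i] += c;
            if (i != j) out[nn * (p - 1) + n * i + j] += c;
          }
          run = 0;
        }
      }
    }
  out.attr("dim") = IntegerVector::create(n, n, L);
  return out;
}

// Dual SMO solver for the soft-margin C-SVC on a precomputed kernel matrix.
// Minimises 0.5 a'Qa - e'a with Q_ij = y_i y_j K_ij subject to y'a = 0 and
// 0 <= a <= C, with second-order working-set selection; stops when the
// KKT duality gap falls below tol.
// [[Rcpp::export]]
List cpp_smo(NumericMatrix K, NumericVector y, double C, double tol,
             int maxit) {
  const int n = K.nrow();
  std::vector<double> a(n, 0.0), G(n, -1.0);
  const double TAU = 1e-12;
  int it = 0;
  bool conv = false;
  double m = 0, M = 0;
  for (it = 0; it < maxit; ++it) {
    int i = -1;
    m = -1e300;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0) ? (a[t] < C) : (a[t] > 0);
      if (up) {
        double v = -y[t] * G[t];
        if (v > m) { m = v; i = t; }
      }
    }
    int j = -1;
    M = 1e300;
    double best = 0;
    for (int t = 0; t < n; ++t) {
      bool low = (y[t] > 0) ? (a[t] > 0) : (a[t] < C);
      if (low) {
        double v = -y[t] * G[t];
        if (v < M) M = v;
        if (i >= 0 && v < m) {
          double qit = K(i, i) + K(t, t) - 2.0 * y[i] * y[t] * K(i, t);
          if (qit <= TAU) qit = TAU;
          double bit = m - v;
          double gain = bit * bit / qit;
          if (gain > best) { best = gain; j = t; }
        }
      }
    }
    if (i < 0 || j < 0 || m - M <= tol) {
      conv = true;
      break;
    }
    double qij = K(i, i) + K(j, j) - 2.0 * y[i] * y[j] * K(i, j);
    if (qij <= TAU) qij = TAU;
    double ai_old = a[i], aj_old = a[j];
    if (y[i] != y[j]) {
      double delta = (-G[i] - G[j]) / qij;
      double diff = a[i] - a[j];
      a[i] += delta;
      a[j] += delta;
      if (diff > 0) {
        if (a[j] < 0) { a[j] = 0; a[i] = diff; }
      } else {
        if (a[i] < 0) { a[i] = 0; a[j] = -diff; }
      }
      if (diff > 0) {
        if (a[i] > C) { a[i] = C; a[j] = C - diff; }
      } else {
        if (a[j] > C) { a[j] = C; a[i] = C + diff; }
      }
    } else {
      double delta = (G[i] - G[j]) / qij;
      double sum = a[i] + a[j];
      a[i] -= delta;
      a[j] += delta;
      if (sum > C) {
        if (a[i] > C) { a[i] = C; a[j] = sum - C; }
      } else {
        if (a[j] < 0) { a[j] = 0; a[i] = sum; }
      }
      if (sum > C) {
        if (a[j] > C) { a[j] = C; a[i] = sum - C; }
      } else {
        if (a[i] < 0) { a[i] = 0; a[j] = sum; }
      }
    }
    double di = y[i] * (a[i] - ai_old), dj = y[j] * (a[j] - aj_old);
    for (int t = 0; t < n; ++t) G[t] += y[t] * (K(i, t) * di + K(j, t) * dj);
  }
  // bias from KKT: average y_i*G_i over free support vectors, else midpoint
  double ub = 1e300, lb = -1e300, sumfree = 0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (a[t] > TAU && a[t] < C - TAU) {
      sumfree += yG;
      ++nfree;
    } else {
      bool up = (y[t] > 0) ? (a[t] < C) : (a[t] > 0);
      bool low = (y[t] > 0) ? (a[t] > 0) : (a[t] < C);
      if (up) lb = std::max(lb, -y[t] * G[t]);
      if (low) ub = std::min(ub, -y[t] * G[t]);
    }
  }
  double rho = (nfree > 0) ? sumfree / nfree : -(ub + lb) / 2.0;
  // dual objective 0.5 a'Qa - e'a = 0.5 (a'G - e'a) since G = Qa - e
  double aG = 0, ae = 0;
  for (int t = 0; t < n; ++t) {
    aG += a[t] * G[t];
    ae += a[t];
  }
  double obj = 0.5 * (aG - ae);
  return List::create(_["alpha"] = a, _["bias"] = -rho, _["iterations"] = it,
                      _["converged"] = conv, _["objective"] = obj,
                      _["gap"] = m - M);
}
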