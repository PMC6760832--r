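#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimization for the linear epsilon-SVR dual:
//   max  -1/2 sum_ij (a_i - a*_i)(a_j - a*_j) K_ij
//        - eps sum_i (a_i + a*_i) + sum_i y_i (a_i - a*_i)
//   s.t. sum_i (a_i - a*_i) = 0,  0 <= a_i, a*_i <= C.
//
// The 2n variables are indexed with t < n the alpha block and t >= n the
// alpha-star block. Writing beta_i = a_i - a*_i and g = K beta, the
// optimality value of variable t is v1_i = y_i - eps - g_i (alpha) or
// v2_i = y_i + eps - g_i (alpha-star); the KKT gap is
// max(I_up) - min(I_low) and the solver stops when it falls below `tol`.
// The first working variable is the maximal violator over I_up; the second
// is chosen by the second-order rule, maximizing the guaranteed objective
// decrease (m - v)^2 / eta over I_low.

struct SmoState {
  std::vector<double> a, as, beta, g;
  double bias = 0.0, kkt_gap = 0.0;
  long iterations = 0;
  bool converged = false;
};

static void smo_core(const NumericMatrix& K, const NumericVector& y,
                     double epsilon, double C, double tol, long max_iter,
                     SmoState& st) {
  const int n = y.size();
  std::vector<double>& a = st.a;
  std::vector<double>& as = st.as;
  std::vector<double>& beta = st.beta;
  std::vector<double>& g = st.g;

  double m = 0.0, M = 0.0;
  long iter = 0;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    m = -HUGE_VAL;
    M = HUGE_VAL;
    int p = -1, ptype = 0;
    for (int i = 0; i < n; ++i) {
      const double v1 = y[i] - epsilon - g[i];
      const double v2 = y[i] + epsilon - g[i];
      if (a[i] < C && v1 > m) { m = v1; p = i; ptype = 0; }
      if (as[i] > 0.0 && v2 > m) { m = v2; p = i; ptype = 1; }
      if (a[i] > 0.0 && v1 < M) M = v1;
      if (as[i] < C && v2 < M) M = v2;
    }
    if (p < 0 || m - M <= tol) { converged = true; break; }

    int q = -1, qtype = 0;
    double best_gain = -1.0, best_v = 0.0, best_eta = 1.0;
    const double Kpp = K(p, p);
    for (int i = 0; i < n; ++i) {
      const double v1 = y[i] - epsilon - g[i];
      const double v2 = y[i] + epsilon - g[i];
      double eta = Kpp + K(i, i) - 2.0 * K(p, i);
      if (eta < 1e-12) eta = 1e-12;
      if (a[i] > 0.0 && v1 < m) {
        const double diff = m - v1;
        const double gain = diff * diff / eta;
        if (gain > best_gain) { best_gain = gain; q = i; qtype = 0; best_v = v1; best_eta = eta; }
      }
      if (as[i] < C && v2 < m) {
        const double diff = m - v2;
        const double gain = diff * diff / eta;
        if (gain > best_gain) { best_gain = gain; q = i; qtype = 1; best_v = v2; best_eta = eta; }
      }
    }
    if (q < 0) { converged = true; break; }

    double d = (m - best_v) / best_eta;
    const double cap_p = (ptype == 0) ? (C - a[p]) : as[p];
    const double cap_q = (qtype == 0) ? a[q] : (C - as[q]);
    if (d > cap_p) d = cap_p;
    if (d > cap_q) d = cap_q;
    if (d <= 0.0) break; // numerically stuck; caller checks the gap

    if (ptype == 0) a[p] += d; else as[p] -= d;
    if (qtype == 0) a[q] -= d; else as[q] += d;
    beta[p] += d;
    beta[q] -= d;
    for (int i = 0; i < n; ++i) g[i] += d * (K(i, p) - K(i, q));
  }

  // bias from KKT: free variables sit exactly on the tube boundary
  double bsum = 0.0;
  int bcount = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] > 0.0 && a[i] < C) { bsum += y[i] - epsilon - g[i]; ++bcount; }
    if (as[i] > 0.0 && as[i] < C) { bsum += y[i] + epsilon - g[i]; ++bcount; }
  }
  if (bcount > 0) st.bias = bsum / bcount;
  else if (std::isfinite(m) && std::isfinite(M)) st.bias = (m + M) / 2.0;
  else st.bias = 0.0;

  st.kkt_gap = (std::isfinite(m) && std::isfinite(M)) ? (m - M) : 0.0;
  st.iterations = iter;
  st.converged = converged;
}

static void init_state(SmoState& st, int n) {
  st.a.assign(n, 0.0);
  st.as.assign(n, 0.0);
  st.beta.assign(n, 0.0);
  st.g.assign(n, 0.0);
}

// Solve one epsilon-SVR dual. A feasible starting point may be supplied
// (`a_init`, `as_init`) to warm-start from a previous solution.
// [[Rcpp::export]]
List smo_svr_solve(NumericMatrix K, NumericVector y, double epsilon, double C,
                   double tol = 1e-8, double max_iter = 50000000,
                   Nullable<NumericVector> a_init = R_NilValue,
                   Nullable<NumericVector> as_init = R_NilValue) {
  const int n = y.size();
  if (K.nrow() != n || K.ncol() != n) stop("K must be n x n");
  SmoState st;
  init_state(st, n);
  if (a_init.isNotNull() && as_init.isNotNull()) {
    NumericVector a0(a_init), as0(as_init);
    if (a0.size() == n && as0.size() == n) {
      bool feasible = true;
      double bal = 0.0;
      for (int i = 0; i < n; ++i) {
        if (a0[i] < 0.0 || a0[i] > C || as0[i] < 0.0 || as0[i] > C) { feasible = false; break; }
        bal += a0[i] - as0[i];
      }
      if (feasible && std::fabs(bal) < 1e-9 * (1.0 + C)) {
        for (int i = 0; i < n; ++i) {
          st.a[i] = a0[i];
          st.as[i] = as0[i];
          st.beta[i] = a0[i] - as0[i];
        }
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          for (int j = 0; j < n; ++j) s += K(i, j) * st.beta[j];
          st.g[i] = s;
        }
      }
    }
  }
  smo_core(K, y, epsilon, C, tol, (long)max_iter, st);
  return List::create(
    _["beta"] = NumericVector(st.beta.begin(), st.beta.end()),
    _["alpha"] = NumericVector(st.a.begin(), st.a.end()),
    _["alpha_star"] = NumericVector(st.as.begin(), st.as.end()),
    _["bias"] = st.bias,
    _["iterations"] = (double)st.iterations,
    _["kkt_gap"] = st.kkt_gap,
    _["converged"] = st.converged);
}

// Grid evaluation for one cross-validation fold: solves the dual for every
// (epsilon, C) pair and accumulates held-out squared errors into `sse`
// (rows = epsilon index, columns = C index). Pairs are visited with C
// ascending in the outer loop and epsilon ascending inside so each
// solution warm-starts the next; this is valid because the feasible box
// only grows with C and epsilon does not enter the constraints.
// `cost_order` and `eps_order` give the ascending visiting order
// (0-based); results land at the original grid positions.
// [[Rcpp::export]]
NumericMatrix smo_svr_grid_fold(NumericMatrix K, NumericVector y,
                                NumericMatrix Kte, NumericVector yte,
                                double ybar,
                                NumericVector epsilon_grid,
                                NumericVector cost_grid,
                                IntegerVector eps_order,
                                IntegerVector cost_order,
                                NumericMatrix sse,
                                double tol = 1e-6, double max_iter = 50000000) {
  const int n = y.size();
  const int nte = yte.size();
  if (K.nrow() != n || K.ncol() != n) stop("K must be n x n");
  if (Kte.nrow() != nte || Kte.ncol() != n) stop("Kte must be nte x n");
  SmoState st;
  init_state(st, n);
  NumericMatrix out(clone(sse));
  long total_iter = 0;
  const int ne = eps_order.size();
  for (int co = 0; co < cost_order.size(); ++co) {
    const int ci = cost_order[co];
    const double C = cost_grid[ci];
    // snake traversal: alternate the epsilon direction per C row so each
    // warm start comes from the nearest previously solved problem
    for (int eo0 = 0; eo0 < ne; ++eo0) {
      const int eo = (co % 2 == 0) ? eo0 : (ne - 1 - eo0);
      const int ei = eps_order[eo];
      smo_core(K, y, epsilon_grid[ei], C, tol, (long)max_iter, st);
      total_iter += st.iterations;
      double err = 0.0;
      for (int t = 0; t < nte; ++t) {
        double f = st.bias + ybar;
        for (int j = 0; j < n; ++j) f += Kte(t, j) * st.beta[j];
        const double r = yte[t] - f;
        err += r * r;
      }
      out(ei, ci) += err;
    }
  }
  out.attr("total_iterations") = (double)total_iter;
  return out;
}
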