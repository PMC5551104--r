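#include <Rcpp.h>
using namespace Rcpp;

// L1-regularized maxent fit by cyclic coordinate descent with
// soft-thresholding and an active-set strategy. Maximizes
//   mean_presence(eta) - log sum_bg exp(eta) - sum_j beta_j * |lambda_j|
// where eta = F lambda. Fb is the background feature matrix (n_bg x p),
// mp the presence feature means (p). Convergence requires a small relative
// objective change on a full sweep plus KKT stationarity within kkt_tol on
// every coordinate.
// [[Rcpp::export]]
List ccd_fit(NumericMatrix Fb, NumericVector mp, NumericVector beta,
             NumericVector lambda_init, double tol, int max_iter,
             double kkt_tol) {
  const int nb = Fb.nrow(), p = Fb.ncol();
  NumericVector lambda = clone(lambda_init);
  std::vector<double> eta(nb, 0.0), w(nb);
  double Z = 0.0, shift = 0.0;

  for (int i = 0; i < nb; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) if (lambda[j] != 0.0) e += Fb(i, j) * lambda[j];
    eta[i] = e;
  }
  auto recompute_w = [&]() {
    shift = *std::max_element(eta.begin(), eta.end());
    Z = 0.0;
    for (int i = 0; i < nb; ++i) { w[i] = std::exp(eta[i] - shift); Z += w[i]; }
  };
  recompute_w();

  auto objective = [&]() {
    double lp = 0.0, pen = 0.0;
    for (int j = 0; j < p; ++j) {
      lp += mp[j] * lambda[j];
      pen += beta[j] * std::fabs(lambda[j]);
    }
    return lp - (std::log(Z) + shift) - pen;
  };

  // one coordinate update; returns |delta|
  auto update_coord = [&](int j) {
    const double *col = &Fb(0, j);
    double Ef = 0.0, Ef2 = 0.0;
    for (int i = 0; i < nb; ++i) {
      double q = w[i], f = col[i];
      Ef += q * f; Ef2 += q * f * f;
    }
    Ef /= Z; Ef2 /= Z;
    double g = mp[j] - Ef;
    double h = std::max(Ef2 - Ef * Ef, 1e-8);
    double u = h * lambda[j] + g;
    double lnew = (u > beta[j]) ? (u - beta[j]) / h
                : (u < -beta[j]) ? (u + beta[j]) / h : 0.0;
    double d = lnew - lambda[j];
    if (d == 0.0) return 0.0;
    if (d > 2.0) d = 2.0; else if (d < -2.0) d = -2.0;  // damp huge steps
    lambda[j] += d;
    Z = 0.0;
    for (int i = 0; i < nb; ++i) {
      eta[i] += d * col[i];
      w[i] = std::exp(eta[i] - shift);
      Z += w[i];
    }
    return std::fabs(d);
  };

  std::vector<char> active(p, 1);
  double obj = objective();
  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    bool full = (iter % 10 == 0);  // periodic full sweep re-screens coordinates
    for (int j = 0; j < p; ++j) {
      if (!full && !active[j]) continue;
      double d = update_coord(j);
      active[j] = (lambda[j] != 0.0 || d != 0.0);
    }
    recompute_w();
    if (!full) continue;
    double obj_new = objective();
    bool obj_ok = std::fabs(obj_new - obj) <= tol * (std::fabs(obj) + 1e-10);
    obj = obj_new;
    if (obj_ok) {
      double viol = 0.0;
      for (int j = 0; j < p; ++j) {
        const double *col = &Fb(0, j);
        double Ef = 0.0;
        for (int i = 0; i < nb; ++i) Ef += w[i] * col[i];
        Ef /= Z;
        double g = mp[j] - Ef;
        double v = (lambda[j] == 0.0)
          ? std::max(0.0, std::fabs(g) - beta[j])
          : std::fabs(g - ((lambda[j] > 0) ? beta[j] : -beta[j]));
        if (v > viol) viol = v;
        if (v > kkt_tol) active[j] = 1;
      }
      if (viol <= kkt_tol) { converged = true; ++iter; break; }
    }
  }
  obj = objective();
  return List::create(_["lambda"] = lambda, _["converged"] = converged,
                      _["iterations"] = iter, _["objective"] = obj);
}

// number of strict inversions (i < j with x[i] > x[j]) by merge sort
// [[Rcpp::export]]
double count_inversions_cpp(NumericVector x) {
  const R_xlen_t n = x.size();
  std::vector<double> a(x.begin(), x.end()), buf(n);
  double inv = 0.0;
  for (R_xlen_t width = 1; width < n; width *= 2) {
    for (R_xlen_t lo = 0; lo + width < n; lo += 2 * width) {
      R_xlen_t mid = lo + width, hi = std::min(lo + 2 * width, n);
      R_xlen_t i = lo, j = mid, k = lo;
      while (i < mid && j < hi) {
        if (a[j] < a[i]) { inv += mid - i; buf[k++] = a[j++]; }
        else buf[k++] = a[i++];
      }
      while (i < mid) buf[k++] = a[i++];
      while (j < hi) buf[k++] = a[j++];
      std::copy(buf.begin() + lo, buf.begin() + hi, a.begin() + lo);
    }
  }
  return inv;
}
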