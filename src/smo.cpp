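#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// SMO-type decomposition solver for the soft-margin SVM dual on a
// precomputed kernel:
//
//   max_a  sum_i a_i - 1/2 sum_ij a_i a_j y_i y_j K_ij
//   s.t.   sum_i a_i y_i = 0,  0 <= a_i <= C_i
//
// Working-set selection is the maximal violating pair over
//   I_up  = {t : (y_t = +1, a_t < C_t) or (y_t = -1, a_t > 0)}
//   I_low = {t : (y_t = +1, a_t > 0)  or (y_t = -1, a_t < C_t)},
// stopping when m(a) - M(a) < tol, which bounds the KKT violation.
// Per-sample upper bounds C_i support weighted / duplicated subjects.

// [[Rcpp::export(name = ".smo_solve")]]
Rcpp::List smo_solve(const arma::mat& K, const arma::vec& y,
                     const arma::vec& C, double tol = 1e-8,
                     int max_iter = 1000000) {
  const arma::uword n = K.n_rows;
  arma::vec alpha(n, arma::fill::zeros);
  // gradient of f(a) = 1/2 a'Qa - e'a with Q_ij = y_i y_j K_ij
  arma::vec G(n);
  G.fill(-1.0);

  int iter = 0;
  double gap = 0.0;
  for (; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    double gmax = -arma::datum::inf, gmin = arma::datum::inf;
    for (arma::uword t = 0; t < n; ++t) {
      const bool pos = y[t] > 0;
      const double v = -y[t] * G[t];
      const bool in_up  = pos ? (alpha[t] < C[t]) : (alpha[t] > 0.0);
      const bool in_low = pos ? (alpha[t] > 0.0)  : (alpha[t] < C[t]);
      if (in_up && v > gmax) { gmax = v; i = (int)t; }
      if (in_low && v < gmin) { gmin = v; j = (int)t; }
    }
    gap = gmax - gmin;
    if (i < 0 || j < 0 || gap < tol) break;

    const double ai_old = alpha[i], aj_old = alpha[j];
    // curvature along the feasible direction; Q_ij = y_i y_j K_ij makes it
    // K_ii + K_jj - 2 K_ij in both label configurations
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0.0) quad = 1e-12;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0.0) {
        if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = -diff; }
      }
      if (diff > C[i] - C[j]) {
        if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = C[i] - diff; }
      } else {
        if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = C[j] + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0.0) quad = 1e-12;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C[i]) {
        if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = sum - C[i]; }
      } else {
        if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = sum; }
      }
      if (sum > C[j]) {
        if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = sum - C[j]; }
      } else {
        if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    for (arma::uword t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }

  // bias: mean of y_i - s_i (= -y_i G_i) over free support vectors;
  // fallback midpoint of the feasible interval from bound constraints
  double b = 0.0;
  int n_free = 0;
  double sum_free = 0.0;
  double ub = arma::datum::inf, lb = -arma::datum::inf;
  for (arma::uword t = 0; t < n; ++t) {
    const double eps_t = 1e-8 * C[t];
    const double v = -y[t] * G[t];
    if (alpha[t] > eps_t && alpha[t] < C[t] - eps_t) {
      sum_free += v;
      ++n_free;
    } else if ((y[t] > 0 && alpha[t] >= C[t] - eps_t) ||
               (y[t] < 0 && alpha[t] <= eps_t)) {
      if (v < ub) ub = v;
    } else {
      if (v > lb) lb = v;
    }
  }
  if (n_free > 0) {
    b = sum_free / n_free;
  } else {
    if (!std::isfinite(ub)) ub = lb;
    if (!std::isfinite(lb)) lb = ub;
    b = (ub + lb) / 2.0;
  }

  // dual objective sum(a) - 1/2 a'Qa = (sum(a) - a'G) / 2
  const double obj = 0.5 * (arma::accu(alpha) - arma::dot(alpha, G));

  return Rcpp::List::create(
      Rcpp::Named("alpha") = alpha, Rcpp::Named("b") = b,
      Rcpp::Named("objective") = obj, Rcpp::Named("iterations") = iter,
      Rcpp::Named("kkt_gap") = gap,
      Rcpp::Named("converged") = iter < max_iter);
}
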