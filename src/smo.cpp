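#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the C-SVC dual:
//   min_a 0.5 a'Qa - e'a,  Q_ij = y_i y_j K_ij,  0 <= a_i <= C,  y'a = 0
// Second-order working-set selection (maximal violator paired with the
// maximal-gain partner), stopping when the KKT violation drops below tol.
// K must be symmetric; column pointers exploit that for cache-friendly
// access. Returns alpha, the offset rho (decision value
// f(x) = sum_i alpha_i y_i K(x, x_i) - rho), and an iteration count.

// A warm start may be supplied through alpha0 (e.g. the solution for a
// smaller C, which stays feasible when C grows); the gradient is then
// rebuilt from it.

// [[Rcpp::export(name = ".smo_csvc")]]
List smo_csvc(NumericMatrix K, IntegerVector y, double C,
              double tol = 1e-3, int max_iter = 1000000,
              NumericVector alpha0 = NumericVector(0)) {
  const int n = y.size();
  const double TAU = 1e-12;
  const double* Kp = REAL(K);
  std::vector<double> alpha(n, 0.0), G(n, -1.0), Kd(n);
  for (int t = 0; t < n; ++t) Kd[t] = Kp[(size_t)t * n + t];
  if (alpha0.size() == n) {
    for (int s = 0; s < n; ++s) {
      alpha[s] = std::min(std::max(alpha0[s], 0.0), C);
      if (alpha[s] > 0) {
        const double* Ks = Kp + (size_t)s * n;
        double c = alpha[s] * y[s];
        for (int t = 0; t < n; ++t) G[t] += y[t] * c * Ks[t];
      }
    }
  }

  int iter = 0;
  bool converged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    double Gmax = -1e300, Gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      if (up && v > Gmax) { Gmax = v; i = t; }
    }
    if (i >= 0) {
      const double* Ki = Kp + (size_t)i * n; // = row i by symmetry
      double best_gain = -1.0;
      for (int t = 0; t < n; ++t) {
        double v = -y[t] * G[t];
        bool low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
        if (!low) continue;
        if (v < Gmin) Gmin = v;
        double b = Gmax - v;
        if (b > 0) {
          double a = Kd[i] + Kd[t] - 2.0 * y[i] * y[t] * Ki[t];
          if (a <= 0) a = TAU;
          double gain = b * b / a;
          if (gain > best_gain) { best_gain = gain; j = t; }
        }
      }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < tol) { converged = true; break; }

    const double* Ki = Kp + (size_t)i * n;
    const double* Kj = Kp + (size_t)j * n;
    double a_i_old = alpha[i], a_j_old = alpha[j];
    if (y[i] != y[j]) {
      double quad = Kd[i] + Kd[j] + 2.0 * Ki[j];
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Kd[i] + Kd[j] - 2.0 * Ki[j];
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double d_i = y[i] * (alpha[i] - a_i_old);
    double d_j = y[j] * (alpha[j] - a_j_old);
    if (d_i != 0.0 || d_j != 0.0) {
      for (int t = 0; t < n; ++t)
        G[t] += y[t] * (Ki[t] * d_i + Kj[t] * d_j);
    }
  }

  // offset rho from the KKT conditions (LIBSVM's calculate_rho)
  double ub = 1e300, lb = -1e300, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= C - 1e-12) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++n_free; sum_free += yG;
    }
  }
  double rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
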