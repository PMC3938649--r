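#include <Rcpp.h>
using namespace Rcpp;

// Closed-form single-accumulator finishing-time CDF of the linear ballistic
// accumulator: start point U[0, A], drift N(nu, s), threshold b.
static inline double node_cdf(double t, double A, double b, double nu, double s) {
  if (t <= 0.0) return 0.0;
  double ts = t * s;
  double u1 = b - A - t * nu;
  double u2 = b - t * nu;
  double F = 1.0 + (u1 / A) * R::pnorm(u1 / ts, 0.0, 1.0, 1, 0)
                 - (u2 / A) * R::pnorm(u2 / ts, 0.0, 1.0, 1, 0)
                 + (ts / A) * R::dnorm(u1 / ts, 0.0, 1.0, 0)
                 - (ts / A) * R::dnorm(u2 / ts, 0.0, 1.0, 0);
  if (F < 0.0) F = 0.0;
  if (F > 1.0) F = 1.0;
  return F;
}

static inline double node_pdf(double t, double A, double b, double nu, double s) {
  if (t <= 0.0) return 0.0;
  double ts = t * s;
  double z1 = (b - A - t * nu) / ts;
  double z2 = (b - t * nu) / ts;
  double f = (-nu * R::pnorm(z1, 0.0, 1.0, 1, 0) + s * R::dnorm(z1, 0.0, 1.0, 0)
              + nu * R::pnorm(z2, 0.0, 1.0, 1, 0) - s * R::dnorm(z2, 0.0, 1.0, 0)) / A;
  return f > 0.0 ? f : 0.0;
}

// Data log-likelihood for one subject, evaluated for several chains at once.
// A, b, s, t0, nu are (5 conditions) x (n chains) matrices on the natural
// scale; nu is the delayed-accumulator mean drift (immediate = 1 - nu).
// choice: 1 = delayed, 0 = immediate; cond: 1-based condition index.
// Log densities below floor_lp (and non-finite values) are clamped.
// [[Rcpp::export]]
NumericVector lba_loglik_chains_cpp(NumericVector rt, IntegerVector choice,
                                    IntegerVector cond,
                                    NumericMatrix A, NumericMatrix b,
                                    NumericMatrix s, NumericMatrix t0,
                                    NumericMatrix nu, double floor_lp) {
  int n = rt.size(), C = A.ncol();
  NumericVector out(C);
  for (int c = 0; c < C; ++c) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      int k = cond[i] - 1;
      double t = rt[i] - t0(k, c);
      double nw = (choice[i] == 1) ? nu(k, c) : 1.0 - nu(k, c);
      double g = node_pdf(t, A(k, c), b(k, c), nw, s(k, c)) *
                 (1.0 - node_cdf(t, A(k, c), b(k, c), 1.0 - nw, s(k, c)));
      double lg = (g > 0.0) ? std::log(g) : floor_lp;
      if (!std::isfinite(lg) || lg < floor_lp) lg = floor_lp;
      acc += lg;
    }
    out[c] = acc;
  }
  return out;
}
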