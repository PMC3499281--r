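#include <Rcpp.h>
using namespace Rcpp;

// Haploid radiation-hybrid hidden Markov chain.
//
// Hidden state: fragment retention (0/1) at each marker along the order.
// Initial distribution: P(1) = r. Between adjacent markers a break occurs
// with probability theta_k; on a break the new fragment is retained with
// probability r, otherwise the state is carried over:
//   P(0->0) = (1-theta) + theta(1-r),  P(0->1) = theta r
//   P(1->0) = theta(1-r),              P(1->1) = (1-theta) + theta r
// Emission: observed call equals the state, flipped with probability eps;
// missing calls (NA) are marginalised.

static const double PAR_LO = 1e-6;
static const double PAR_HI = 1.0 - 1e-6;

static inline double clamp01(double x) {
  if (x < PAR_LO) return PAR_LO;
  if (x > PAR_HI) return PAR_HI;
  return x;
}

// emission probability of the observed call given state
static inline void emis(int obs, double eps, double& e0, double& e1) {
  if (obs == NA_INTEGER) { e0 = 1.0; e1 = 1.0; }
  else if (obs == 1)     { e0 = eps; e1 = 1.0 - eps; }
  else                   { e0 = 1.0 - eps; e1 = eps; }
}

// Forward log-likelihood over all clones.
// calls: n_clones x m integer matrix with entries 1/0/NA.
// [[Rcpp::export]]
double cpp_rh_loglik(IntegerMatrix calls, NumericVector theta, double r,
                     double eps) {
  int n = calls.nrow(), m = calls.ncol();
  if (theta.size() != m - 1) stop("theta must have length m-1");
  double ll = 0.0;
  for (int c = 0; c < n; ++c) {
    double e0, e1;
    emis(calls(c, 0), eps, e0, e1);
    double a0 = (1.0 - r) * e0, a1 = r * e1;
    double sc = a0 + a1;
    ll += std::log(sc); a0 /= sc; a1 /= sc;
    for (int k = 1; k < m; ++k) {
      double th = theta[k - 1];
      double p00 = (1.0 - th) + th * (1.0 - r), p01 = th * r;
      double p10 = th * (1.0 - r), p11 = (1.0 - th) + th * r;
      emis(calls(c, k), eps, e0, e1);
      double b0 = (a0 * p00 + a1 * p10) * e0;
      double b1 = (a0 * p01 + a1 * p11) * e1;
      sc = b0 + b1;
      ll += std::log(sc);
      a0 = b0 / sc; a1 = b1 / sc;
    }
  }
  return ll;
}

// EM fit of per-interval theta and a single panel-wide retention r.
// Convergence when the log-likelihood gain drops below tol.
// [[Rcpp::export]]
List cpp_rh_em(IntegerMatrix calls, NumericVector theta0, double r0,
               double eps, double tol, int max_iter, bool update_r) {
  int n = calls.nrow(), m = calls.ncol();
  if (theta0.size() != m - 1) stop("theta0 must have length m-1");
  NumericVector theta = clone(theta0);
  for (int k = 0; k < m - 1; ++k) theta[k] = clamp01(theta[k]);
  double r = clamp01(r0);

  std::vector<double> A0(m), A1(m), B0(m), B1(m), SC(m);
  double ll = R_NegInf;
  int it = 0;
  bool converged = false;

  for (it = 1; it <= max_iter; ++it) {
    std::vector<double> brk(m - 1, 0.0);   // expected breaks per interval
    double new_ret = 0.0;                  // retained new-fragment draws
    double new_tot = 0.0;                  // total new-fragment draws
    double ll_new = 0.0;

    for (int c = 0; c < n; ++c) {
      double e0, e1;
      // forward (scaled)
      emis(calls(c, 0), eps, e0, e1);
      A0[0] = (1.0 - r) * e0; A1[0] = r * e1;
      SC[0] = A0[0] + A1[0];
      A0[0] /= SC[0]; A1[0] /= SC[0];
      for (int k = 1; k < m; ++k) {
        double th = theta[k - 1];
        double p00 = (1.0 - th) + th * (1.0 - r), p01 = th * r;
        double p10 = th * (1.0 - r), p11 = (1.0 - th) + th * r;
        emis(calls(c, k), eps, e0, e1);
        double b0 = (A0[k - 1] * p00 + A1[k - 1] * p10) * e0;
        double b1 = (A0[k - 1] * p01 + A1[k - 1] * p11) * e1;
        double sc = b0 + b1;
        A0[k] = b0 / sc; A1[k] = b1 / sc; SC[k] = sc;
        ll_new += std::log(sc);
      }
      ll_new += std::log(SC[0]);
      // backward (scaled by same SC)
      B0[m - 1] = 1.0; B1[m - 1] = 1.0;
      for (int k = m - 2; k >= 0; --k) {
        double th = theta[k];
        double p00 = (1.0 - th) + th * (1.0 - r), p01 = th * r;
        double p10 = th * (1.0 - r), p11 = (1.0 - th) + th * r;
        emis(calls(c, k + 1), eps, e0, e1);
        B0[k] = (p00 * e0 * B0[k + 1] + p01 * e1 * B1[k + 1]) / SC[k + 1];
        B1[k] = (p10 * e0 * B0[k + 1] + p11 * e1 * B1[k + 1]) / SC[k + 1];
      }
      // initial-state posterior: one new-fragment draw per clone
      double g1 = A1[0] * B1[0] / (A0[0] * B0[0] + A1[0] * B1[0]);
      new_ret += g1;
      new_tot += 1.0;
      // transition posteriors
      for (int k = 0; k < m - 1; ++k) {
        double th = theta[k];
        double p00 = (1.0 - th) + th * (1.0 - r), p01 = th * r;
        double p10 = th * (1.0 - r), p11 = (1.0 - th) + th * r;
        emis(calls(c, k + 1), eps, e0, e1);
        double x00 = A0[k] * p00 * e0 * B0[k + 1] / SC[k + 1];
        double x01 = A0[k] * p01 * e1 * B1[k + 1] / SC[k + 1];
        double x10 = A1[k] * p10 * e0 * B0[k + 1] / SC[k + 1];
        double x11 = A1[k] * p11 * e1 * B1[k + 1] / SC[k + 1];
        double z = x00 + x01 + x10 + x11;
        x00 /= z; x01 /= z; x10 /= z; x11 /= z;
        // probability a break occurred given the transition
        double b_same0 = th * (1.0 - r) / p00;
        double b_same1 = th * r / p11;
        double b = x01 + x10 + x00 * b_same0 + x11 * b_same1;
        brk[k] += b;
        new_ret += x01 + x11 * b_same1;
        new_tot += b;
      }
    }

    // M-step
    for (int k = 0; k < m - 1; ++k) theta[k] = clamp01(brk[k] / n);
    if (update_r) r = clamp01(new_ret / new_tot);

    if (it > 1 && std::fabs(ll_new - ll) < tol) {
      ll = ll_new; converged = true; break;
    }
    ll = ll_new;
  }
  // one clean forward pass at the final parameters
  ll = cpp_rh_loglik(calls, theta, r, eps);
  return List::create(_["loglik"] = ll, _["theta"] = theta, _["r"] = r,
                      _["iterations"] = it, _["converged"] = converged);
}

// two-marker joint log-likelihood under the equal-retention model
static inline double tp_ll(double a, double bc, double d, double th,
                           double r) {
  double p11 = r * (1.0 - th) + r * r * th;
  double p10 = r * th * (1.0 - r);
  double p00 = (1.0 - r) * (1.0 - th) + (1.0 - r) * (1.0 - r) * th;
  return a * std::log(p11) + bc * std::log(p10) + d * std::log(p00);
}

static double golden_theta(double a, double bc, double d, double r) {
  const double gr = 0.6180339887498949;
  double lo = PAR_LO, hi = PAR_HI;
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = tp_ll(a, bc, d, x1, r), f2 = tp_ll(a, bc, d, x2, r);
  for (int i = 0; i < 80; ++i) {
    if (f1 < f2) {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo); f2 = tp_ll(a, bc, d, x2, r);
    } else {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo); f1 = tp_ll(a, bc, d, x1, r);
    }
  }
  return 0.5 * (lo + hi);
}

static double golden_r(double a, double bc, double d, double th) {
  const double gr = 0.6180339887498949;
  double lo = PAR_LO, hi = PAR_HI;
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = tp_ll(a, bc, d, th, x1), f2 = tp_ll(a, bc, d, th, x2);
  for (int i = 0; i < 80; ++i) {
    if (f1 < f2) {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo); f2 = tp_ll(a, bc, d, th, x2);
    } else {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo); f1 = tp_ll(a, bc, d, th, x1);
    }
  }
  return 0.5 * (lo + hi);
}

// Batch two-point MLE over 2x2 presence tables.
// Returns theta_hat, r_hat, loglik at the optimum and the LOD against
// the independence model (theta = 1, shared marginal retention).
// [[Rcpp::export]]
DataFrame cpp_two_point(NumericVector n11, NumericVector n10,
                        NumericVector n01, NumericVector n00) {
  int np = n11.size();
  NumericVector th_out(np), r_out(np), ll_out(np), lod_out(np);
  for (int i = 0; i < np; ++i) {
    double a = n11[i], bc = n10[i] + n01[i], d = n00[i];
    double n = a + bc + d;
    double r = clamp01((2.0 * a + bc) / (2.0 * n));
    double th = clamp01(bc / std::max(2.0 * r * (1.0 - r) * n, 1e-12));
    double ll_prev = tp_ll(a, bc, d, th, r);
    for (int iter = 0; iter < 60; ++iter) {
      th = golden_theta(a, bc, d, r);
      r = golden_r(a, bc, d, th);
      double ll = tp_ll(a, bc, d, th, r);
      if (std::fabs(ll - ll_prev) < 1e-10) { ll_prev = ll; break; }
      ll_prev = ll;
    }
    double r1 = clamp01((2.0 * a + bc) / (2.0 * n));
    double ll0 = tp_ll(a, bc, d, 1.0 - 1e-12, r1);
    double lod = (ll_prev - ll0) / std::log(10.0);
    th_out[i] = th; r_out[i] = r; ll_out[i] = ll_prev;
    lod_out[i] = lod > 0.0 ? lod : 0.0;
  }
  return DataFrame::create(_["theta_hat"] = th_out, _["r_hat"] = r_out,
                           _["loglik"] = ll_out, _["lod"] = lod_out);
}
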