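// Two-dimensional Epileptor reduction used as the generative model for MAP
// inversion: per region, du1/dt = 1 - u1^3 - 2 u1^2 - v + I1 + GC * (C S(u1))_i
// and dv/dt = (4 (u1 - u0) - v)/tau0, with a Heaviside firing rate S on the
// presynaptic node.  The reduction inherits the full model's time constants,
// so it is integrated on the recording's millisecond axis from the shared
// interictal initial state; the predicted observation samples are the states
// at the substep indices in `rec_idx` (the feature-window sample times).
// Explicit Euler with a substep well inside the fast subsystem's stability
// limit.
//
// The log-posterior gradient is computed with the discrete adjoint of the
// Euler scheme; the Heaviside is piecewise constant so its contribution to
// the state Jacobian is zero almost everywhere.

#include <RcppArmadillo.h>
using namespace Rcpp;

// Forward integration; records u1 at the substep indices in rec_idx
// (1-based: index m means the state after m Euler substeps).  Optionally
// keeps the full substep trajectory for the adjoint pass.
static bool fwd2d(const arma::vec& u0, double gc, const arma::mat& C,
                  double thGC, double I1, double tau0,
                  double dt, const arma::uvec& rec_idx,
                  double u1_init, double v_init,
                  bool keep_traj,
                  arma::mat& u1s, arma::mat& cvecs, arma::mat& u1samp) {
  const arma::uword R = u0.n_elem;
  const arma::uword M = rec_idx.max();
  const arma::uword n_out = rec_idx.n_elem;
  if (keep_traj) {
    u1s.set_size(R, M + 1);
    cvecs.set_size(R, M);     // coupling input used in step m (col m-1)
  }
  u1samp.set_size(R, n_out);
  arma::vec u1(R), v(R);
  u1.fill(u1_init);
  v.fill(v_init);
  if (keep_traj) u1s.col(0) = u1;
  // the Heaviside firing vector changes rarely, so the connectome input
  // C * S is recomputed only when a region crosses the threshold
  std::vector<signed char> S(R, 2);  // force initial recompute
  arma::vec cvec(R, arma::fill::zeros);
  arma::uword next_rec = 0;
  bool finite_ok = true;
  for (arma::uword m = 1; m <= M; ++m) {
    bool changed = false;
    for (arma::uword i = 0; i < R; ++i) {
      const signed char s = u1(i) >= thGC ? 1 : 0;
      if (s != S[i]) { S[i] = s; changed = true; }
    }
    if (changed) {
      cvec.zeros();
      for (arma::uword j = 0; j < R; ++j) {
        if (S[j]) cvec += C.col(j);
      }
    }
    if (keep_traj) cvecs.col(m - 1) = cvec;
    double umax = 0.0;
    for (arma::uword i = 0; i < R; ++i) {
      const double ui = u1(i), vi = v(i);
      const double du = 1.0 - ui * ui * ui - 2.0 * ui * ui - vi + I1
                        + gc * cvec(i);
      const double dv = (4.0 * (ui - u0(i)) - vi) / tau0;
      u1(i) = ui + dt * du;
      v(i) = vi + dt * dv;
      const double au = std::abs(u1(i));
      if (au > umax) umax = au;
      if (!std::isfinite(u1(i))) finite_ok = false;
    }
    if (keep_traj) u1s.col(m) = u1;
    while (next_rec < n_out && rec_idx(next_rec) == m) {
      u1samp.col(next_rec) = u1;
      ++next_rec;
    }
    if (!finite_ok || umax > 1e3) return false;
  }
  return true;
}

// [[Rcpp::export]]
arma::mat predict2d_cpp(const arma::vec& u0, double gc, const arma::mat& C,
                        double thGC, double I1, double tau0,
                        double dt, const arma::uvec& rec_idx,
                        double u1_init, double v_init) {
  arma::mat u1s, cvecs, u1samp;
  if (!fwd2d(u0, gc, C, thGC, I1, tau0, dt, rec_idx, u1_init, v_init,
             false, u1s, cvecs, u1samp))
    u1samp.fill(arma::datum::nan);
  return u1samp;
}

// Log-posterior (Gaussian likelihood over all contacts x samples, unit-sd
// normal prior kernels, no normalization constants) and its gradient with
// respect to theta = (u0[1..R], gc, amplitude, offset, log-floor).
// Observation model: source power mixes linearly through the (squared-gain)
// mixing matrix G, a global floor phi = exp(lfl) plays the role the
// dynamic-range floor plays in the envelope extraction, and the prediction
// is the baseline-shifted log power
//   yhat_k(t) = amp * (log(sum_j G_kj exp(u1_j(t)) + phi)
//               - log(sum_j G_kj exp(u1_init) + phi)) + off.
// [[Rcpp::export]]
List logpost2d_cpp(const arma::vec& u0, double gc, double amp, double off,
                   double lfl,
                   const arma::mat& y, const arma::mat& G, const arma::mat& C,
                   double thGC, double I1, double tau0,
                   double dt, const arma::uvec& rec_idx,
                   double u1_init, double v_init, double sigma,
                   double pr_u0_mu, double pr_u0_sd,
                   double pr_gc_mu, double pr_gc_sd,
                   double pr_amp_mu, double pr_amp_sd,
                   double pr_off_mu, double pr_off_sd,
                   double pr_lfl_mu, double pr_lfl_sd) {
  const arma::uword R = u0.n_elem;
  const arma::uword M = rec_idx.max();
  const double sig2 = sigma * sigma;

  arma::mat u1s, cvecs, u1samp;
  const bool ok = fwd2d(u0, gc, C, thGC, I1, tau0, dt, rec_idx,
                        u1_init, v_init, true, u1s, cvecs, u1samp);
  if (!ok) {
    return List::create(_["value"] = R_NegInf,
                        _["grad"] = arma::vec(R + 4, arma::fill::zeros),
                        _["ok"] = false);
  }
  const double phi = std::exp(lfl);
  arma::mat E = arma::exp(u1samp);             // R x n_out
  arma::mat S1 = G * E + phi;                  // K x n_out
  arma::mat L = arma::log(S1);
  // channel baseline at the shared interictal state: observed envelopes sit
  // on a common floor, so the prediction is the baseline-shifted log power
  arma::vec B0 = G * arma::vec(G.n_cols,
                               arma::fill::value(std::exp(u1_init))) + phi;
  L.each_col() -= arma::log(B0);
  arma::mat yhat = amp * L + off;
  arma::mat resid = y - yhat;

  double lp = -0.5 * arma::accu(arma::square(resid)) / sig2
              - 0.5 * arma::accu(arma::square((u0 - pr_u0_mu) / pr_u0_sd))
              - 0.5 * std::pow((gc - pr_gc_mu) / pr_gc_sd, 2)
              - 0.5 * std::pow((amp - pr_amp_mu) / pr_amp_sd, 2)
              - 0.5 * std::pow((off - pr_off_mu) / pr_off_sd, 2)
              - 0.5 * std::pow((lfl - pr_lfl_mu) / pr_lfl_sd, 2);

  // direct adjoint of the recorded samples:
  // dL/du1_j[t] = amp/sig2 * sum_k resid_kt G_kj exp(u1_j[t]) / S1_kt
  arma::mat RS = resid / S1;                   // K x n_out
  arma::mat d = (amp / sig2) * (G.t() * RS) % E;   // R x n_out
  // floor gradient: phi enters every S1 entry and every channel baseline
  double grad_lfl = (amp * phi / sig2) *
    (arma::accu(RS) - arma::dot(arma::sum(resid, 1), 1.0 / B0))
    - (lfl - pr_lfl_mu) / (pr_lfl_sd * pr_lfl_sd);

  arma::vec lamU(R, arma::fill::zeros), lamV(R, arma::fill::zeros);
  arma::vec grad_u0(R, arma::fill::zeros);
  double grad_gc = 0.0;
  const double ratio = 4.0 * dt / tau0;
  arma::sword rec_ptr = (arma::sword)rec_idx.n_elem - 1;
  for (arma::uword m = M; m >= 1; --m) {
    while (rec_ptr >= 0 && rec_idx((arma::uword)rec_ptr) == m) {
      lamU += d.col((arma::uword)rec_ptr);
      --rec_ptr;
    }
    const double* u1m = u1s.colptr(m - 1);
    const double* cv = cvecs.colptr(m - 1);
    for (arma::uword i = 0; i < R; ++i) {
      const double lu = lamU(i), lv = lamV(i);
      grad_gc += dt * lu * cv[i];
      grad_u0(i) -= ratio * lv;
      const double a = 1.0 + dt * (-3.0 * u1m[i] * u1m[i] - 4.0 * u1m[i]);
      lamU(i) = lu * a + lv * ratio;
      lamV(i) = -dt * lu + lv * (1.0 - dt / tau0);
    }
  }
  grad_u0 += -(u0 - pr_u0_mu) / (pr_u0_sd * pr_u0_sd);
  grad_gc += -(gc - pr_gc_mu) / (pr_gc_sd * pr_gc_sd);
  double grad_amp = arma::accu(resid % L) / sig2
                    - (amp - pr_amp_mu) / (pr_amp_sd * pr_amp_sd);
  double grad_off = arma::accu(resid) / sig2
                    - (off - pr_off_mu) / (pr_off_sd * pr_off_sd);

  arma::vec grad(R + 4);
  grad.subvec(0, R - 1) = grad_u0;
  grad(R) = grad_gc;
  grad(R + 1) = grad_amp;
  grad(R + 2) = grad_off;
  grad(R + 3) = grad_lfl;
  return List::create(_["value"] = lp, _["grad"] = grad, _["ok"] = true);
}
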