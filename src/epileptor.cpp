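// Fixed-step RK4 integrator for the 5-population Epileptor network, used both
// as a neural field (cortical vertices with a sparse local coupling kernel,
// plus point-source subcortical nodes) and as a pure neural mass (one node per
// region).  The exponential-kernel integral feeding the spike-wave population
// is realized as an auxiliary sixth state g with dg/dt = -g/tau12 + a12*u1 +
// LC*gamma12*(w*S(u1,th12)), which is the exact ODE form of the integral.
//
// To keep memory flat at high resolution, the SEEG projection (gain %*%
// observable, batched into a level-3 BLAS call every few hundred samples)
// and per-node onset latencies are accumulated online; full per-node traces
// are stored only for an explicitly requested node subset.

#include <RcppArmadillo.h>
using namespace Rcpp;

struct EpiPar {
  double I1, I2, g11, g22, g12, th11, thGC, th22, th12, tau0, tau2, tau12, a12;
};

static EpiPar unpack(const List& par) {
  EpiPar p;
  p.I1 = par["I1"];     p.I2 = par["I2"];
  p.g11 = par["gamma11"]; p.g22 = par["gamma22"]; p.g12 = par["gamma12"];
  p.th11 = par["theta11"]; p.thGC = par["thetaGC"];
  p.th22 = par["theta22"]; p.th12 = par["theta12"];
  p.tau0 = par["tau0"]; p.tau2 = par["tau2"]; p.tau12 = par["tau12"];
  p.a12 = par["a12"];
  return p;
}

// preallocated scratch shared by the four RK4 stage evaluations
struct EpiWork {
  arma::vec S1, S22, l1, l22, l12, usum, cvec;
  EpiWork(arma::uword n, arma::uword nreg)
    : S1(n), S22(n), l1(n), l22(n), l12(n), usum(nreg), cvec(nreg) {}
};

// state columns: 0 u1, 1 u2, 2 v, 3 q1, 4 q2, 5 g
static void epi_deriv(const arma::mat& s, arma::mat& ds, EpiWork& w,
                      const EpiPar& p, const arma::vec& u0,
                      double lc, double gc,
                      const arma::sp_mat& W, bool use_W,
                      const arma::mat& C,
                      const arma::uvec& node_region,
                      const arma::vec& local_on,
                      const arma::uvec& region_count) {
  const arma::uword n = s.n_rows, nreg = C.n_rows;
  for (arma::uword i = 0; i < n; ++i) {
    w.S1(i)  = s(i, 0) >= p.th11 ? 1.0 : 0.0;
    w.S22(i) = s(i, 3) >= p.th22 ? 1.0 : 0.0;
  }
  const bool loc = use_W && lc != 0.0;
  if (loc) {
    // S is a 0/1 vector that is mostly zero (only firing vertices), so
    // W * S is accumulated over the active columns of the CSC kernel
    auto conv = [&](const arma::vec& S, arma::vec& out) {
      out.zeros();
      for (arma::uword j = 0; j < n; ++j) {
        if (S(j) == 0.0) continue;
        for (arma::sp_mat::const_col_iterator it = W.begin_col(j);
             it != W.end_col(j); ++it) {
          out(it.row()) += *it;
        }
      }
    };
    // th12 == th11 in the default parameter set, so the w*S(u1) convolution
    // is shared between the fast and the exponential-kernel local terms
    conv(w.S1, w.l1);
    if (p.th12 == p.th11) {
      w.l12 = (lc * p.g12) * w.l1;
    } else {
      arma::vec S12(n);
      for (arma::uword i = 0; i < n; ++i)
        S12(i) = s(i, 0) >= p.th12 ? 1.0 : 0.0;
      conv(S12, w.l12);
      w.l12 *= lc * p.g12;
    }
    conv(w.S22, w.l22);
    w.l22 *= lc * p.g22;
    w.l1 *= lc * p.g11;
    w.l1 %= local_on; w.l22 %= local_on; w.l12 %= local_on;
  }
  // region-mean fast activity, then firing rate and connectome input
  w.usum.zeros();
  for (arma::uword i = 0; i < n; ++i) w.usum(node_region(i)) += s(i, 0);
  for (arma::uword r = 0; r < nreg; ++r)
    w.usum(r) = (w.usum(r) / region_count(r)) >= p.thGC ? 1.0 : 0.0;
  w.cvec = C * w.usum;

  for (arma::uword i = 0; i < n; ++i) {
    const double u1 = s(i, 0), u2 = s(i, 1), v = s(i, 2),
                 q1 = s(i, 3), q2 = s(i, 4), g = s(i, 5);
    const double f1 = (u1 < 0.0)
      ? (u1 * u1 * u1 - 3.0 * u1 * u1)
      : ((q1 - 0.6 * (v - 4.0) * (v - 4.0)) * u1);
    const double f2 = (q1 < -0.25) ? 0.0 : 6.0 * (q1 + 0.25);
    ds(i, 0) = u2 - f1 - v + p.I1 + (loc ? w.l1(i) : 0.0)
               + gc * w.cvec(node_region(i));
    ds(i, 1) = 1.0 - 5.0 * u1 * u1 - u2;
    ds(i, 2) = (4.0 * (u1 - u0(i)) - v) / p.tau0;
    ds(i, 3) = -q2 + q1 - q1 * q1 * q1 + p.I2 + 0.002 * g
               - 0.3 * (v - 3.5) + (loc ? w.l22(i) : 0.0);
    ds(i, 4) = (-q2 + f2) / p.tau2;
    ds(i, 5) = -g / p.tau12 + p.a12 * u1 + (loc ? w.l12(i) : 0.0);
  }
}

// [[Rcpp::export]]
List epi_simulate_cpp(const arma::vec& u0, const List& par,
                      double lc, double gc,
                      const arma::sp_mat& W, bool use_W,
                      const arma::mat& C,
                      const arma::uvec& node_region,
                      const arma::vec& local_on,
                      const arma::mat& init,
                      double dt, int n_samples,
                      const arma::mat& gain, bool use_gain,
                      const arma::uvec& record_nodes,
                      bool record_u1,
                      double onset_threshold) {
  const EpiPar p = unpack(par);
  const arma::uword n = u0.n_elem, nreg = C.n_rows;
  if (init.n_rows != n || init.n_cols != 6)
    stop("init must be n_nodes x 6");
  arma::uvec region_count(nreg, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) region_count(node_region(i)) += 1;
  if (arma::any(region_count == 0)) stop("empty region in node_region");

  arma::mat s = init;
  arma::mat k1(n, 6), k2(n, 6), k3(n, 6), k4(n, 6), tmp(n, 6);
  EpiWork w(n, nreg);

  const arma::uword nrec = record_nodes.n_elem;
  arma::mat obs_rec(nrec, (arma::uword)n_samples);
  arma::mat u1_rec(record_u1 ? nrec : 0, (arma::uword)n_samples);
  arma::mat seeg;
  const arma::uword batch = 256;
  arma::mat obs_buf;
  arma::uword buf_fill = 0, buf_start = 0;
  if (use_gain) {
    seeg.set_size(gain.n_rows, (arma::uword)n_samples);
    obs_buf.set_size(n, batch);
  }
  arma::vec onset(n); onset.fill(NA_REAL);

  bool ok = true;
  for (int t = 0; t < n_samples; ++t) {
    epi_deriv(s, k1, w, p, u0, lc, gc, W, use_W, C, node_region, local_on,
              region_count);
    tmp = s + 0.5 * dt * k1;
    epi_deriv(tmp, k2, w, p, u0, lc, gc, W, use_W, C, node_region, local_on,
              region_count);
    tmp = s + 0.5 * dt * k2;
    epi_deriv(tmp, k3, w, p, u0, lc, gc, W, use_W, C, node_region, local_on,
              region_count);
    tmp = s + dt * k3;
    epi_deriv(tmp, k4, w, p, u0, lc, gc, W, use_W, C, node_region, local_on,
              region_count);
    s += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);

    if (!s.is_finite() || arma::abs(s.col(0)).max() > 1e3) {
      ok = false;
      break;
    }
    const double tnow = dt * (t + 1);
    for (arma::uword i = 0; i < n; ++i)
      if (!arma::is_finite(onset(i)) && s(i, 0) > onset_threshold)
        onset(i) = tnow;
    if (use_gain) {
      obs_buf.col(buf_fill++) = s.col(3) - s.col(0);
      if (buf_fill == batch) {
        seeg.cols(buf_start, buf_start + batch - 1) =
          gain * obs_buf;
        buf_start += batch;
        buf_fill = 0;
      }
    }
    for (arma::uword j = 0; j < nrec; ++j) {
      obs_rec(j, t) = s(record_nodes(j), 3) - s(record_nodes(j), 0);
      if (record_u1) u1_rec(j, t) = s(record_nodes(j), 0);
    }
  }
  if (use_gain && ok && buf_fill > 0) {
    seeg.cols(buf_start, buf_start + buf_fill - 1) =
      gain * obs_buf.cols(0, buf_fill - 1);
  }

  List out = List::create(
    _["ok"] = ok,
    _["onset"] = onset,
    _["final_state"] = s);
  out["seeg"] = use_gain ? wrap(seeg) : R_NilValue;
  if (nrec > 0) {
    out["obs"] = obs_rec;
    out["u1"] = record_u1 ? wrap(u1_rec) : R_NilValue;
  } else {
    out["obs"] = R_NilValue;
    out["u1"] = R_NilValue;
  }
  return out;
}
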