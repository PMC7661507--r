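#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Photon-by-photon likelihood of a two-state kinetic model.
//
// The likelihood of a trace is 1' prod_i [ n_{c_i} exp((K - nD - nA) tau_i) ] p_eq,
// propagated left to right with per-photon renormalization; the log of the
// accumulated norms is the log-likelihood. For two states the propagator
// exp(M tau) is evaluated in closed form from the eigenvalues of M.
//
// State order: (U, B); column convention dp/dt = K p.

struct TwoStateModel {
  double a, b, c, d;       // entries of M = K - nD - nA
  double nD[2], nA[2];
  double peq[2];
  TwoStateModel(double kon, double koff,
                double nDU, double nDB, double nAU, double nAB) {
    nD[0] = nDU; nD[1] = nDB; nA[0] = nAU; nA[1] = nAB;
    a = -(kon + nDU + nAU); b = koff;
    c = kon;                d = -(koff + nDB + nAB);
    double s = kon + koff;
    if (s > 0) { peq[0] = koff / s; peq[1] = kon / s; }
    else { peq[0] = 1.0; peq[1] = 0.0; }
  }
  // v <- exp(M tau) v
  inline void propagate(double tau, double &v0, double &v1) const {
    double mean = 0.5 * (a + d);
    double diff = 0.5 * (a - d);
    double disc = std::sqrt(diff * diff + b * c);
    double e1, e2, w0, w1;
    if (disc * tau > 1e-9) {
      double ep = std::exp((mean + disc) * tau);
      double em = std::exp((mean - disc) * tau);
      double cosh_ = 0.5 * (ep + em);
      double sinh_ = 0.5 * (ep - em) / disc;   // sinh(disc*tau)/disc scaled
      // exp(M tau) = cosh(disc t) I + sinh(disc t)/disc (M - mean I), all times e^{mean t}
      e1 = cosh_ + sinh_ * diff;   // [0][0]
      e2 = cosh_ - sinh_ * diff;   // [1][1]
      w0 = sinh_ * b;              // [0][1]
      w1 = sinh_ * c;              // [1][0]
    } else {
      // nearly defective: first-order series around mean
      double emt = std::exp(mean * tau);
      e1 = emt * (1.0 + diff * tau);
      e2 = emt * (1.0 - diff * tau);
      w0 = emt * b * tau;
      w1 = emt * c * tau;
    }
    double nv0 = e1 * v0 + w0 * v1;
    double nv1 = w1 * v0 + e2 * v1;
    v0 = nv0; v1 = nv1;
  }
};

// [[Rcpp::export]]
double cpp_loglik2(NumericVector tau, IntegerVector color,
                   double kon, double koff,
                   double nDU, double nDB, double nAU, double nAB) {
  const int n = tau.size();
  if (n == 0) return 0.0;
  TwoStateModel m(kon, koff, nDU, nDB, nAU, nAB);
  double v0 = m.peq[0], v1 = m.peq[1];
  double logl = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i > 0) m.propagate(tau[i], v0, v1);
    if (color[i] == 0) { v0 *= m.nD[0]; v1 *= m.nD[1]; }
    else               { v0 *= m.nA[0]; v1 *= m.nA[1]; }
    double s = v0 + v1;
    if (!(s > 0.0) || !std::isfinite(s)) return R_NegInf;
    logl += std::log(s);
    v0 /= s; v1 /= s;
  }
  return logl;
}

// Per-trace log-likelihoods for an ensemble sharing (kon, koff) but with
// trace-specific emission rates (rows of em: nDU, nDB, nAU, nAB).
// [[Rcpp::export]]
NumericVector cpp_loglik2_traces(List taus, List colors,
                                 double kon, double koff, NumericMatrix em) {
  const int J = taus.size();
  NumericVector out(J);
  for (int j = 0; j < J; ++j) {
    NumericVector tau = taus[j];
    IntegerVector col = colors[j];
    out[j] = cpp_loglik2(tau, col, kon, koff,
                         em(j, 0), em(j, 1), em(j, 2), em(j, 3));
  }
  return out;
}

// Viterbi path (most likely state per photon) for the two-state model,
// using the same per-interval propagators as the likelihood, in log domain.
// Returns 1 for U, 2 for B per photon.
// [[Rcpp::export]]
IntegerVector cpp_viterbi2(NumericVector tau, IntegerVector color,
                           double kon, double koff,
                           double nDU, double nDB, double nAU, double nAB) {
  const int n = tau.size();
  IntegerVector path(n);
  if (n == 0) return path;
  TwoStateModel m(kon, koff, nDU, nDB, nAU, nAB);

  std::vector<unsigned char> back0(n), back1(n);
  double d0, d1; // log delta
  {
    double e0 = (color[0] == 0 ? m.nD[0] : m.nA[0]) * m.peq[0];
    double e1 = (color[0] == 0 ? m.nD[1] : m.nA[1]) * m.peq[1];
    d0 = e0 > 0 ? std::log(e0) : R_NegInf;
    d1 = e1 > 0 ? std::log(e1) : R_NegInf;
  }
  for (int i = 1; i < n; ++i) {
    // propagator entries for this interval
    double p00 = 1, p01 = 0, p10 = 0, p11 = 1;
    {
      double v0 = 1, v1 = 0; m.propagate(tau[i], v0, v1); p00 = v0; p10 = v1;
      v0 = 0; v1 = 1; m.propagate(tau[i], v0, v1); p01 = v0; p11 = v1;
    }
    double le0 = color[i] == 0 ? (m.nD[0] > 0 ? std::log(m.nD[0]) : R_NegInf)
                               : (m.nA[0] > 0 ? std::log(m.nA[0]) : R_NegInf);
    double le1 = color[i] == 0 ? (m.nD[1] > 0 ? std::log(m.nD[1]) : R_NegInf)
                               : (m.nA[1] > 0 ? std::log(m.nA[1]) : R_NegInf);
    double l00 = p00 > 0 ? std::log(p00) : R_NegInf;
    double l01 = p01 > 0 ? std::log(p01) : R_NegInf;
    double l10 = p10 > 0 ? std::log(p10) : R_NegInf;
    double l11 = p11 > 0 ? std::log(p11) : R_NegInf;
    double c00 = d0 + l00, c01 = d1 + l01;   // into state 0
    double c10 = d0 + l10, c11 = d1 + l11;   // into state 1
    double nd0, nd1;
    if (c00 >= c01) { nd0 = c00 + le0; back0[i] = 0; }
    else            { nd0 = c01 + le0; back0[i] = 1; }
    if (c11 >= c10) { nd1 = c11 + le1; back1[i] = 1; }
    else            { nd1 = c10 + le1; back1[i] = 0; }
    d0 = nd0; d1 = nd1;
    // renormalize to avoid drift to -inf
    double mx = std::max(d0, d1);
    if (std::isfinite(mx)) { d0 -= mx; d1 -= mx; }
  }
  int s = d1 > d0 ? 1 : 0;
  path[n - 1] = s + 1;
  for (int i = n - 1; i > 0; --i) {
    s = (s == 0) ? back0[i] : back1[i];
    path[i - 1] = s + 1;
  }
  return path;
}

// Exact stochastic (Gillespie) trajectory of a continuous-time Markov chain.
// K is the generator (column convention); returns switch times and states.
// Uses R's RNG so that set.seed() controls reproducibility.
// [[Rcpp::export]]
List cpp_simulate_ctmc(NumericMatrix K, double duration, int state0) {
  const int n = K.nrow();
  std::vector<double> times; std::vector<int> states;
  double t = 0.0; int s = state0 - 1;
  times.push_back(0.0); states.push_back(s + 1);
  while (t < duration) {
    double rout = -K(s, s);
    if (rout <= 0) break;             // absorbing state
    double dt = R::exp_rand() / rout;
    t += dt;
    if (t >= duration) break;
    double u = R::unif_rand() * rout, acc = 0.0; int nxt = s;
    for (int k = 0; k < n; ++k) {
      if (k == s) continue;
      acc += K(k, s);
      if (u <= acc) { nxt = k; break; }
    }
    s = nxt;
    times.push_back(t); states.push_back(s + 1);
  }
  return List::create(_["t"] = times, _["state"] = states,
                      _["duration"] = duration);
}
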