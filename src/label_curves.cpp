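#include <Rcpp.h>
using namespace Rcpp;

// C++ port of the exact exponential-sum solution of the label-kinetics
// ODEs (linear states driven by the piecewise-exponential water curve).
// Mirrors the R implementation in R/expsum.R; kept in lockstep by tests
// that compare the two routes.

namespace {

struct ES {
  std::vector<double> c, r;
  void add_term(double coef, double rate) {
    for (size_t i = 0; i < r.size(); i++) {
      if (r[i] == rate) { c[i] += coef; return; }
    }
    c.push_back(coef); r.push_back(rate);
  }
};

ES es_scale(const ES& a, double s) {
  ES out = a;
  for (auto& x : out.c) x *= s;
  return out;
}

ES es_add(const ES& a, const ES& b) {
  ES out = a;
  for (size_t i = 0; i < b.c.size(); i++) out.add_term(b.c[i], b.r[i]);
  return out;
}

double es_eval(const ES& a, double t) {
  double s = 0.0;
  for (size_t i = 0; i < a.c.size(); i++) s += a.c[i] * std::exp(a.r[i] * t);
  return s;
}

// y' = -lambda y + f(t), y(t0) = y0; resonant denominators nudged as in R.
ES es_solve_linear(double lambda, const ES& f, double y0, double t0) {
  ES part;
  for (size_t i = 0; i < f.c.size(); i++) {
    double denom = lambda + f.r[i];
    double eps = 1e-9 * std::max(std::fabs(lambda) + std::fabs(f.r[i]), 1e-12);
    if (std::fabs(denom) < eps) denom = (denom >= 0) ? eps : -eps;
    part.add_term(f.c[i] / denom, f.r[i]);
  }
  double k0 = (y0 - es_eval(part, t0)) * std::exp(lambda * t0);
  part.add_term(k0, -lambda);
  return part;
}

struct PES { ES p1, p2; double tau; };

double pes_eval(const PES& s, double t) {
  return (t <= s.tau) ? es_eval(s.p1, t) : es_eval(s.p2, t);
}

// water curve as two exponential sums
void water_es(double f_r, double dw, double beta, double tau,
              ES& u1, ES& u2) {
  u1.add_term(f_r, 0.0);
  u1.add_term(beta - f_r, -dw);
  double u_tau = es_eval(u1, tau);
  u2.add_term(u_tau * std::exp(dw * tau), -dw);
}

PES solve_state(double lambda, double u_coef, double a_tn,
                const PES& ftn, const ES& u1, const ES& u2, double tau) {
  PES out; out.tau = tau;
  ES f1 = es_add(es_scale(u1, u_coef), es_scale(ftn.p1, a_tn));
  out.p1 = es_solve_linear(lambda, f1, 0.0, 0.0);
  double y_tau = es_eval(out.p1, tau);
  ES f2 = es_add(es_scale(u2, u_coef), es_scale(ftn.p2, a_tn));
  out.p2 = es_solve_linear(lambda, f2, y_tau, tau);
  return out;
}

PES solve_ftn(double p_n, double c, double dn_loss,
              const ES& u1, const ES& u2, double tau) {
  PES out; out.tau = tau;
  out.p1 = es_solve_linear(dn_loss, es_scale(u1, p_n * c), 0.0, 0.0);
  double y_tau = es_eval(out.p1, tau);
  out.p2 = es_solve_linear(dn_loss, es_scale(u2, p_n * c), y_tau, tau);
  return out;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix label_curves_implicit_fast(double p_n, double dn_loss,
                                         double p_s, double ds_star,
                                         double delta_ratio, double k,
                                         double c, double f_r, double dw,
                                         double beta, double tau,
                                         NumericVector times) {
  ES u1, u2;
  water_es(f_r, dw, beta, tau, u1, u2);
  PES ftn = solve_ftn(p_n, c, dn_loss, u1, u2, tau);
  double k2 = std::pow(2.0, k);
  double u_coef = (delta_ratio * (k2 - 1.0) + p_s) * c;
  PES fs = solve_state(ds_star, u_coef, delta_ratio, ftn, u1, u2, tau);
  int nt = times.size();
  NumericMatrix out(nt, 2);
  for (int i = 0; i < nt; i++) {
    out(i, 0) = pes_eval(ftn, times[i]);
    out(i, 1) = pes_eval(fs, times[i]);
  }
  colnames(out) = CharacterVector::create("F_TN", "F_TSCM");
  return out;
}

// [[Rcpp::export]]
NumericMatrix label_curves_explicit_fast(double p_n, double dn_loss,
                                         double p_s1, double d_s1,
                                         double p_s2, double d_s2,
                                         double a1, double a2, double k,
                                         double c, double f_r, double dw,
                                         double beta, double tau,
                                         NumericVector times) {
  ES u1, u2;
  water_es(f_r, dw, beta, tau, u1, u2);
  PES ftn = solve_ftn(p_n, c, dn_loss, u1, u2, tau);
  double k2 = std::pow(2.0, k);
  PES fs1 = solve_state(d_s1, (a1 * (k2 - 1.0) + p_s1) * c, a1, ftn, u1, u2, tau);
  PES fs2 = solve_state(d_s2, (a2 * (k2 - 1.0) + p_s2) * c, a2, ftn, u1, u2, tau);
  int nt = times.size();
  NumericMatrix out(nt, 3);
  for (int i = 0; i < nt; i++) {
    out(i, 0) = pes_eval(ftn, times[i]);
    out(i, 1) = pes_eval(fs1, times[i]);
    out(i, 2) = pes_eval(fs2, times[i]);
  }
  colnames(out) = CharacterVector::create("F_TN", "F_TSCM1", "F_TSCM2");
  return out;
}
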