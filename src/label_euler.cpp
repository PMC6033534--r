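#include <Rcpp.h>
using namespace Rcpp;

// Brute-force fixed-step (forward Euler) integration of the label-fraction
// ODEs.  Deliberately naive: serves as an independent oracle for the exact
// exponential-sum solver in tests, never as a production path.

static inline double U_of_t(double t, double f_r, double delta_w,
                            double beta_s, double tau) {
  if (t <= tau) return f_r * (1.0 - std::exp(-delta_w * t)) +
                       beta_s * std::exp(-delta_w * t);
  double u_tau = f_r * (1.0 - std::exp(-delta_w * tau)) +
                 beta_s * std::exp(-delta_w * tau);
  return u_tau * std::exp(-delta_w * (t - tau));
}

// [[Rcpp::export]]
NumericMatrix euler_label_implicit_cpp(double p_n, double dn_loss, double p_s,
                                       double ds_star, double delta_ratio,
                                       double k, double c,
                                       double f_r, double delta_w,
                                       double beta_s, double tau,
                                       NumericVector times, double dt) {
  int nt = times.size();
  NumericMatrix out(nt, 2);
  double k2 = std::pow(2.0, k);
  double ftn = 0.0, fs = 0.0, t = 0.0;
  int j = 0;
  while (j < nt && times[j] <= 0.0) { out(j, 0) = 0.0; out(j, 1) = 0.0; j++; }
  double tmax = times[nt - 1];
  while (t < tmax && j < nt) {
    double u = U_of_t(t, f_r, delta_w, beta_s, tau);
    double cu = c * u;
    double dftn = p_n * cu - dn_loss * ftn;
    double dfs = delta_ratio * ((k2 - 1.0) * cu + ftn) + p_s * cu - ds_star * fs;
    ftn += dt * dftn;
    fs += dt * dfs;
    t += dt;
    while (j < nt && times[j] <= t + 1e-12) {
      out(j, 0) = ftn; out(j, 1) = fs; j++;
    }
  }
  colnames(out) = CharacterVector::create("F_TN", "F_TSCM");
  return out;
}

// [[Rcpp::export]]
NumericMatrix euler_label_explicit_cpp(double p_n, double dn_loss,
                                       double p_s1, double d_s1,
                                       double p_s2, double d_s2,
                                       double a1, double a2,
                                       double k, double c,
                                       double f_r, double delta_w,
                                       double beta_s, double tau,
                                       NumericVector times, double dt) {
  int nt = times.size();
  NumericMatrix out(nt, 3);
  double k2 = std::pow(2.0, k);
  double ftn = 0.0, f1 = 0.0, f2 = 0.0, t = 0.0;
  int j = 0;
  while (j < nt && times[j] <= 0.0) { j++; }
  double tmax = times[nt - 1];
  while (t < tmax && j < nt) {
    double u = U_of_t(t, f_r, delta_w, beta_s, tau);
    double cu = c * u;
    double dftn = p_n * cu - dn_loss * ftn;
    double df1 = a1 * ((k2 - 1.0) * cu + ftn - k2 * f1) + p_s1 * (cu - f1);
    double df2 = a2 * ((k2 - 1.0) * cu + ftn - k2 * f2) + p_s2 * (cu - f2);
    ftn += dt * dftn; f1 += dt * df1; f2 += dt * df2;
    t += dt;
    while (j < nt && times[j] <= t + 1e-12) {
      out(j, 0) = ftn; out(j, 1) = f1; out(j, 2) = f2; j++;
    }
  }
  colnames(out) = CharacterVector::create("F_TN", "F_TSCM1", "F_TSCM2");
  return out;
}
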