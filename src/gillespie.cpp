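#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of a linear birth-death clone.
// Events: division at rate x*p, disappearance at rate x*d; waiting times are
// exponential with rate S = x*(p+d).  Uses R's RNG so set.seed() governs.

// [[Rcpp::export]]
List gillespie_clone_cpp(double n0, double p, double d, double max_time,
                         bool record = false, int record_every = 1) {
  double x = n0;
  double t = 0.0;
  const double half_target = n0 / 2.0;
  double half_life = NA_REAL;
  if (x <= half_target) half_life = 0.0;
  double extinction = NA_REAL;
  bool censored = false;

  std::vector<double> rec_t, rec_x;
  long long ev = 0;
  if (record) { rec_t.push_back(0.0); rec_x.push_back(x); }

  if (x <= 0.0) {
    extinction = 0.0;
  } else if (p + d <= 0.0) {
    censored = true;  // no events possible: degenerate trajectory
    t = max_time;
  } else {
    const double pr_div = p / (p + d);
    while (x > 0.0) {
      double S = x * (p + d);
      t += R::rexp(1.0 / S);
      if (t > max_time) { t = max_time; censored = true; break; }
      if (R::unif_rand() < pr_div) x += 1.0; else x -= 1.0;
      ev++;
      if (record && (ev % record_every == 0 || x <= 0.0)) {
        rec_t.push_back(t); rec_x.push_back(x);
      }
      if (ISNA(half_life) && x <= half_target) half_life = t;
      if (x <= 0.0) { extinction = t; break; }
    }
  }

  List out = List::create(
    _["extinction_time"] = extinction,
    _["half_life"] = half_life,
    _["censored"] = censored,
    _["final_size"] = x,
    _["n_events"] = (double)ev);
  if (record) {
    out["trajectory_t"] = wrap(rec_t);
    out["trajectory_x"] = wrap(rec_x);
  }
  return out;
}

// Batch of independent runs; returns a matrix with one row per run:
// extinction_time, half_life, censored (0/1), final_size.
// [[Rcpp::export]]
NumericMatrix gillespie_runs_cpp(double n0, double p, double d,
                                 double max_time, int n_runs) {
  NumericMatrix out(n_runs, 4);
  for (int i = 0; i < n_runs; i++) {
    List r = gillespie_clone_cpp(n0, p, d, max_time, false, 1);
    out(i, 0) = as<double>(r["extinction_time"]);
    out(i, 1) = as<double>(r["half_life"]);
    out(i, 2) = as<bool>(r["censored"]) ? 1.0 : 0.0;
    out(i, 3) = as<double>(r["final_size"]);
  }
  colnames(out) = CharacterVector::create("extinction_time", "half_life",
                                          "censored", "final_size");
  return out;
}
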