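#' Parameters of the one-pool (implicit-heterogeneity) label model
#'
#' Kinetic parameters for the linear naive -> TSCM differentiation model in
#' which the TSCM pool is described as a single compartment.  At steady state
#' the bulk disappearance rate is not free but derived from the inputs,
#' `d_s = 2^k * delta_ratio + p_s`.  The disappearance rate of *labelled*
#' TSCM DNA, `ds_star`, is free in the implicit-heterogeneity variant;
#' setting it equal to the derived `d_s` (the default, `ds_star = NULL`)
#' imposes kinetic homogeneity.
#'
#' @param p_n Naive proliferation rate, per day (>= 0).  Under naive
#'   homogeneity this is also the loss rate of labelled naive DNA.
#' @param p_s TSCM proliferation (self-renewal) rate, per day (>= 0).
#' @param delta_ratio The product `Delta * T_N / T_SCM`: the per-day flux of
#'   naive cells recruited into the TSCM pool, expressed relative to TSCM
#'   pool size (>= 0).  The label observables depend on `Delta` and the pool
#'   sizes only through this product, so it is the fitted quantity.
#' @param k Number of divisions in the clonal burst accompanying
#'   differentiation (integer, 0-20); each recruited naive cell yields
#'   `2^k` TSCM cells.
#' @param c Amplification factor linking body-water enrichment to the
#'   maximum achievable DNA enrichment (> 0).
#' @param ds_star Disappearance rate of labelled TSCM DNA, per day.  `NULL`
#'   (default) derives it from the homogeneity constraint.
#' @param dn_loss Loss rate of labelled naive DNA, per day.  `NULL` (default)
#'   equals `p_n` (kinetic homogeneity of the naive pool); supplying a free
#'   value relaxes that assumption.
#' @param Delta,ratio_NS Optional absolute recruitment fraction (per day) and
#'   pool-size ratio `T_N / T_SCM`.  Only needed for quantities involving
#'   absolute sizes (e.g. clone seeding); when both are given their product
#'   must equal `delta_ratio`.
#'
#' @return An object of class `implicit_params` with the derived bulk rate
#'   `d_s` attached.
#' @examples
#' implicit_params(p_n = 5e-4, p_s = 0.01, delta_ratio = 0.005, k = 2)
#' @export
implicit_params <- function(p_n, p_s, delta_ratio, k, c = 1,
                            ds_star = NULL, dn_loss = NULL,
                            Delta = NULL, ratio_NS = NULL) {
  stopifnot(p_n >= 0, p_s >= 0, delta_ratio >= 0, c > 0)
  check_k(k)
  d_s <- 2^k * delta_ratio + p_s
  homogeneous <- is.null(ds_star)
  if (homogeneous) ds_star <- d_s
  stopifnot(ds_star >= 0)
  if (is.null(dn_loss)) dn_loss <- p_n
  if (!is.null(Delta) && !is.null(ratio_NS)) {
    if (abs(Delta * ratio_NS - delta_ratio) > 1e-8 * max(delta_ratio, 1e-12)) {
      abort("`Delta * ratio_NS` must equal `delta_ratio`.")
    }
  }
  structure(
    list(p_n = p_n, p_s = p_s, delta_ratio = delta_ratio, k = k, c = c,
         ds_star = ds_star, d_s = d_s, dn_loss = dn_loss,
         homogeneous = homogeneous, Delta = Delta, ratio_NS = ratio_NS),
    class = "implicit_params"
  )
}

check_k <- function(k) {
  if (k < 0 || k > 20 || abs(k - round(k)) > 1e-8) {
    abort("`k` must be an integer between 0 and 20.")
  }
}

#' @export
print.implicit_params <- function(x, ...) {
  cat(sprintf("Implicit-heterogeneity label model (%s variant)\n",
              if (x$homogeneous) "homogeneous" else "heterogeneous"))
  cat(sprintf("  p_n = %.4g  p_s = %.4g  Delta*TN/TSCM = %.4g  k = %d  c = %.3g\n",
              x$p_n, x$p_s, x$delta_ratio, as.integer(x$k), x$c))
  cat(sprintf("  derived d_s = %.4g /d   ds* = %.4g /d\n", x$d_s, x$ds_star))
  invisible(x)
}

#' Parameters of the explicit two-subpopulation label model
#'
#' Kinetic parameters for the variant in which the TSCM pool consists of two
#' kinetically distinct subpopulations.  A fraction `1 - f` of each clonal
#' burst enters the fast subpopulation (rates `p_s1`, `d_s1`) and a fraction
#' `f` enters the slow one (`p_s2`, `d_s2`).  Stationarity of the
#' subpopulation sizes requires `d_si > p_si`; the per-size recruitment
#' fluxes and the relative subpopulation sizes are then fully determined by
#' the rates and `f`, so they are derived rather than free.
#'
#' @inheritParams implicit_params
#' @param f Fraction of each clonal burst entering the slow subpopulation
#'   (0-1).
#' @param p_s1,d_s1 Proliferation and disappearance rates of the fast
#'   subpopulation, per day.
#' @param p_s2,d_s2 Proliferation and disappearance rates of the slow
#'   subpopulation, per day.
#' @param Delta Optional absolute recruitment fraction of naive cells, per
#'   day; needed only for absolute clone-size calculations.
#'
#' @return An object of class `explicit_params` with derived per-size fluxes
#'   (`a1 = Delta (1-f) T_N / T_SCM1`, `a2 = Delta f T_N / T_SCM2`) and the
#'   relative size of the slow subpopulation attached.
#' @examples
#' explicit_params(p_n = 5e-4, f = 0.058, k = 5,
#'                 p_s1 = 0.015, d_s1 = 0.015 + log(2) / (0.41 * 365.25),
#'                 p_s2 = 0.002, d_s2 = 0.002 + log(2) / (8.74 * 365.25))
#' @export
explicit_params <- function(p_n, f, p_s1, d_s1, p_s2, d_s2, k, c = 1,
                            dn_loss = NULL, Delta = NULL) {
  stopifnot(p_n >= 0, p_s1 >= 0, p_s2 >= 0, c > 0, f >= 0, f <= 1)
  check_k(k)
  if (d_s1 <= p_s1 || d_s2 <= p_s2) {
    abort("stationary subpopulations require `d_si > p_si` for i = 1, 2.")
  }
  if (is.null(dn_loss)) dn_loss <- p_n
  a1 <- (d_s1 - p_s1) / 2^k   # Delta*(1-f)*T_N/T_SCM1 at steady state
  a2 <- (d_s2 - p_s2) / 2^k   # Delta*f*T_N/T_SCM2
  # T_SCMi proportional to (fraction entering) / (net loss rate)
  w1 <- (1 - f) / (d_s1 - p_s1)
  w2 <- f / (d_s2 - p_s2)
  rel_size_slow <- if (w1 + w2 > 0) w2 / (w1 + w2) else NA_real_
  structure(
    list(p_n = p_n, f = f, p_s1 = p_s1, d_s1 = d_s1, p_s2 = p_s2,
         d_s2 = d_s2, k = k, c = c, dn_loss = dn_loss,
         a1 = a1, a2 = a2, rel_size_slow = rel_size_slow, Delta = Delta),
    class = "explicit_params"
  )
}

#' @export
print.explicit_params <- function(x, ...) {
  cat("Explicit two-subpopulation label model\n")
  cat(sprintf("  p_n = %.4g  f = %.4g  k = %d  c = %.3g\n",
              x$p_n, x$f, as.integer(x$k), x$c))
  cat(sprintf("  fast: p_s1 = %.4g  d_s1 = %.4g  (half-life %.3g y)\n",
              x$p_s1, x$d_s1, clonal_half_life(x$d_s1, x$p_s1) / DAYS_PER_YEAR))
  cat(sprintf("  slow: p_s2 = %.4g  d_s2 = %.4g  (half-life %.3g y)\n",
              x$p_s2, x$d_s2, clonal_half_life(x$d_s2, x$p_s2) / DAYS_PER_YEAR))
  cat(sprintf("  slow relative size T_SCM2/T_SCM = %.3g\n", x$rel_size_slow))
  invisible(x)
}

# ---- solvers -----------------------------------------------------------------

check_times <- function(times) {
  if (any(times < 0)) abort("`times` must be non-negative.")
  if (is.unsorted(times)) abort("`times` must be ascending.")
}

# Generic TSCM-type state: F' = forcing_coef * U + a * F_TN - lambda * F
fs_solution <- function(lambda, u_coef, a_tn, ftn, water, u = water_pes(water)) {
  tau <- water$tau
  f1 <- es_add(es_scale(u$pieces[[1]], u_coef), es_scale(ftn$pieces[[1]], a_tn))
  p1 <- es_solve_linear(lambda, f1, 0, 0)
  y_tau <- es_eval(p1, tau)
  f2 <- es_add(es_scale(u$pieces[[2]], u_coef), es_scale(ftn$pieces[[2]], a_tn))
  p2 <- es_solve_linear(lambda, f2, y_tau, tau)
  pes_new(c(0, tau), list(p1, p2))
}

# Fast internal paths backed by the C++ port of the exponential-sum solver;
# these carry the whole per-evaluation cost of the least-squares objective.
# The pure-R route below (label_curves_*_r_) is the same algebra in R and is
# held in lockstep by tests.
label_curves_implicit_ <- function(params, water, times) {
  m <- label_curves_implicit_fast(params$p_n, params$dn_loss, params$p_s,
                                  params$ds_star, params$delta_ratio,
                                  params$k, params$c, water$f_r,
                                  water$delta_w, water$beta_s, water$tau,
                                  times)
  list(F_TN = m[, 1L], F_TSCM = m[, 2L])
}

label_curves_explicit_ <- function(params, water, times) {
  m <- label_curves_explicit_fast(params$p_n, params$dn_loss, params$p_s1,
                                  params$d_s1, params$p_s2, params$d_s2,
                                  params$a1, params$a2, params$k, params$c,
                                  water$f_r, water$delta_w, water$beta_s,
                                  water$tau, times)
  F1 <- m[, 2L]
  F2 <- m[, 3L]
  w2 <- params$rel_size_slow
  list(F_TN = m[, 1L], F_TSCM1 = F1, F_TSCM2 = F2,
       F_TSCM = (1 - w2) * F1 + w2 * F2)
}

label_curves_implicit_r_ <- function(params, water, times) {
  u <- water_pes(water)
  a <- params$delta_ratio
  ftn <- ftn_solution_(params$p_n, params$c, params$dn_loss, water, u)
  u_coef <- (a * (2^params$k - 1) + params$p_s) * params$c
  fscm <- fs_solution(params$ds_star, u_coef, a, ftn, water, u)
  list(F_TN = pes_eval(ftn, times), F_TSCM = pes_eval(fscm, times))
}

label_curves_explicit_r_ <- function(params, water, times) {
  u <- water_pes(water)
  k2 <- 2^params$k
  ftn <- ftn_solution_(params$p_n, params$c, params$dn_loss, water, u)
  u1 <- (params$a1 * (k2 - 1) + params$p_s1) * params$c
  u2 <- (params$a2 * (k2 - 1) + params$p_s2) * params$c
  f1 <- fs_solution(params$d_s1, u1, params$a1, ftn, water, u)
  f2 <- fs_solution(params$d_s2, u2, params$a2, ftn, water, u)
  F1 <- pes_eval(f1, times)
  F2 <- pes_eval(f2, times)
  w2 <- params$rel_size_slow
  list(F_TN = pes_eval(ftn, times), F_TSCM1 = F1, F_TSCM2 = F2,
       F_TSCM = (1 - w2) * F1 + w2 * F2)
}

ftn_solution_ <- function(p_n, c, dn_loss, water, u) {
  tau <- water$tau
  p1 <- es_solve_linear(dn_loss, es_scale(u$pieces[[1]], p_n * c), 0, 0)
  y_tau <- es_eval(p1, tau)
  p2 <- es_solve_linear(dn_loss, es_scale(u$pieces[[2]], p_n * c), y_tau, tau)
  pes_new(c(0, tau), list(p1, p2))
}

#' Solve the homogeneous / implicit-heterogeneity label model
#'
#' Computes the fractions of labelled DNA in the naive and TSCM pools over
#' time, driven by the body-water availability curve, with zero initial
#' label.  The default solver is the exact piecewise exponential-sum
#' solution of the linear system; `method = "lsoda"` integrates the same
#' equations numerically (rtol 1e-8, atol 1e-10) as a cross-check.
#'
#' @param params An [implicit_params()] object.
#' @param water A [body_water_params()] object.
#' @param times Ascending, non-negative times in days.
#' @param method `"analytic"` (default) or `"lsoda"`.
#' @return A tibble with columns `time_days`, `F_TN`, `F_TSCM`.
#' @examples
#' bw <- body_water_params(0.05, 0.1, 0.01)
#' pars <- implicit_params(p_n = 5e-4, p_s = 0.01, delta_ratio = 0.005, k = 2)
#' solve_label_implicit(pars, bw, times = seq(0, 300, by = 10))
#' @export
solve_label_implicit <- function(params, water, times,
                                 method = c("analytic", "lsoda")) {
  stopifnot(inherits(params, "implicit_params"),
            inherits(water, "body_water_params"))
  check_times(times)
  method <- match.arg(method)
  a <- params$delta_ratio
  if (method == "analytic") {
    sol <- label_curves_implicit_(params, water, times)
    tibble::tibble(time_days = times, F_TN = sol$F_TN, F_TSCM = sol$F_TSCM)
  } else {
    deriv <- function(t, y, parms) {
      u <- water_enrichment(t, water)
      list(c(
        params$p_n * params$c * u - params$dn_loss * y[1],
        a * ((2^params$k - 1) * params$c * u + y[1]) +
          params$p_s * params$c * u - params$ds_star * y[2]
      ))
    }
    out <- solve_lsoda(deriv, c(0, 0), times)
    tibble::tibble(time_days = times, F_TN = out[, 2], F_TSCM = out[, 3])
  }
}

#' Solve the explicit two-subpopulation label model
#'
#' As [solve_label_implicit()], for the model with two kinetically distinct
#' TSCM subpopulations.  The measurable bulk TSCM fraction is returned as the
#' steady-state-size-weighted mean of the subpopulation fractions, since the
#' sorter sees a single TSCM gate.
#'
#' @param params An [explicit_params()] object.
#' @inheritParams solve_label_implicit
#' @return A tibble with columns `time_days`, `F_TN`, `F_TSCM1`, `F_TSCM2`
#'   and the bulk observable `F_TSCM`.
#' @export
solve_label_explicit <- function(params, water, times,
                                 method = c("analytic", "lsoda")) {
  stopifnot(inherits(params, "explicit_params"),
            inherits(water, "body_water_params"))
  check_times(times)
  method <- match.arg(method)
  k2 <- 2^params$k
  if (method == "analytic") {
    sol <- label_curves_explicit_(params, water, times)
    out <- tibble::tibble(time_days = times, F_TN = sol$F_TN,
                          F_TSCM1 = sol$F_TSCM1, F_TSCM2 = sol$F_TSCM2)
  } else {
    deriv <- function(t, y, parms) {
      u <- water_enrichment(t, water)
      cu <- params$c * u
      list(c(
        params$p_n * cu - params$dn_loss * y[1],
        params$a1 * ((k2 - 1) * cu + y[1] - k2 * y[2]) +
          params$p_s1 * (cu - y[2]),
        params$a2 * ((k2 - 1) * cu + y[1] - k2 * y[3]) +
          params$p_s2 * (cu - y[3])
      ))
    }
    out <- solve_lsoda(deriv, c(0, 0, 0), times)
    out <- tibble::tibble(time_days = times, F_TN = out[, 2],
                          F_TSCM1 = out[, 3], F_TSCM2 = out[, 4])
  }
  w2 <- params$rel_size_slow
  out$F_TSCM <- (1 - w2) * out$F_TSCM1 + w2 * out$F_TSCM2
  out
}

solve_lsoda <- function(deriv, y0, times) {
  t0_added <- times[1] > 0
  tt <- if (t0_added) c(0, times) else times
  out <- deSolve::lsoda(y0, tt, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (attr(out, "istate")[1] < 0) {
    abort("ODE integration failed to converge; see deSolve diagnostics.")
  }
  if (t0_added) out[-1, , drop = FALSE] else out
}

#' Derived bulk rates of the one-pool model
#'
#' Summarises where new TSCM cells come from at steady state: the total
#' replacement rate `d_s = 2^k * delta_ratio + p_s` (per day, per unit pool
#' size), the fraction of newly generated TSCM cells that originate from
#' naive-cell differentiation, and its complement, the self-renewal fraction.
#'
#' @param params An [implicit_params()] object.
#' @return A one-row tibble with columns `d_s`, `replacement_rate`,
#'   `fraction_from_naive`, `fraction_self_renewal`.
#' @export
derived_bulk_rates <- function(params) {
  stopifnot(inherits(params, "implicit_params"))
  influx_naive <- 2^params$k * params$delta_ratio
  total <- influx_naive + params$p_s
  frac_naive <- if (total > 0) influx_naive / total else NA_real_
  tibble::tibble(
    d_s = params$d_s,
    replacement_rate = total,
    fraction_from_naive = frac_naive,
    fraction_self_renewal = 1 - frac_naive
  )
}

#' Collapse an explicit parameter set to its bulk one-pool equivalent
#'
#' When the two subpopulations share identical rates the explicit model is
#' exactly a one-pool model; more generally this returns the size-weighted
#' aggregate used for comparison.
#'
#' @param params An [explicit_params()] object.
#' @return An [implicit_params()] object with size-weighted `p_s`, matched
#'   total naive influx, and `ds_star` equal to the size-weighted
#'   disappearance rate.
#' @export
collapse_explicit <- function(params) {
  stopifnot(inherits(params, "explicit_params"))
  w2 <- params$rel_size_slow
  w1 <- 1 - w2
  p_s <- w1 * params$p_s1 + w2 * params$p_s2
  d_s <- w1 * params$d_s1 + w2 * params$d_s2
  delta_ratio <- (d_s - p_s) / 2^params$k
  implicit_params(p_n = params$p_n, p_s = p_s, delta_ratio = delta_ratio,
                  k = params$k, c = params$c, ds_star = d_s,
                  dn_loss = params$dn_loss)
}
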