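#' Telomere-model parameters
#'
#' @param delta_bp Base pairs lost per cell division.  Defaults to 50, within
#'   the reported plausible range of 35-70 bp/division, which is enforced.
#' @param C Telomerase compensation: the number of clonal-burst divisions
#'   that *do* cost telomere length.  `C = 0` means full compensation (no
#'   shortening during the burst); `C = k` means no compensation.  Must lie
#'   in `[0, k]` for the model it is used with (checked at use time).
#' @return An object of class `telomere_params`.
#' @examples
#' telomere_params(delta_bp = 50, C = 1)
#' @export
telomere_params <- function(delta_bp = 50, C = 0) {
  if (delta_bp < 35 || delta_bp > 70) {
    abort("`delta_bp` must lie in the plausible range [35, 70] bp/division.")
  }
  if (C < 0) abort("`C` must be non-negative.")
  structure(list(delta_bp = delta_bp, C = C), class = "telomere_params")
}

check_C <- function(telo, k) {
  if (telo$C > k + 1e-9) abort("telomerase compensation `C` must not exceed `k`.")
}

#' Steady-state telomere-length difference between TSCM and naive pools
#'
#' The division-counting model predicts that, at steady state, the mean
#' telomere length of TSCM cells falls short of (or exceeds) the naive mean
#' by
#' \deqn{\Theta = C\delta + \frac{(p_s - p_n)\,\delta}{2^{k-1}\, \Delta T_N / T_{SCM}}}
#' in base pairs, with the sign convention that positive \eqn{\Theta} means
#' TSCM cells have divided more.  Here `Delta * T_N / T_SCM` is the
#' `delta_ratio` of the one-pool model.
#'
#' @param params An [implicit_params()] object.
#' @param telo A [telomere_params()] object.
#' @return Steady-state theta in base pairs.
#' @examples
#' pars <- implicit_params(p_n = 5e-4, p_s = 0.01, delta_ratio = 1e-3, k = 1)
#' theta_steady_state(pars, telomere_params(C = 0))
#' @export
theta_steady_state <- function(params, telo) {
  stopifnot(inherits(params, "implicit_params"), inherits(telo, "telomere_params"))
  check_C(telo, params$k)
  if (params$delta_ratio <= 0) {
    abort("steady-state theta is undefined when the naive influx is zero (`delta_ratio` = 0).")
  }
  telo$C * telo$delta_bp +
    (params$p_s - params$p_n) * telo$delta_bp / (2^(params$k - 1) * params$delta_ratio)
}

#' Dynamics of the telomere-length difference
#'
#' The mean-division ODEs reduce to a linear equation for
#' \eqn{\Theta = \delta(\mu_{TSCM} - \mu_{TN})}:
#' \deqn{\dot\Theta = 2(p_s - p_n)\delta - 2^k \frac{\Delta T_N}{T_{SCM}} (\Theta - C\delta),}
#' an exponential approach to the steady state of [theta_steady_state()] at
#' rate `2^k * delta_ratio`.  The closed-form trajectory is returned together
#' with a convergence check at the final time.
#'
#' @inheritParams theta_steady_state
#' @param t_span Times (days) at which to report theta.
#' @param theta0 Initial theta in base pairs (default 0: both pools start
#'   with the same divisional history).
#' @return A tibble with columns `time_days` and `theta_bp`, with attributes
#'   `steady_state` (the fixed point), `rate` (per day) and `converged`
#'   (whether the final value is within 1% of the fixed point).
#' @export
theta_dynamics <- function(params, telo, t_span = seq(0, 3000, by = 10),
                           theta0 = 0) {
  stopifnot(inherits(params, "implicit_params"), inherits(telo, "telomere_params"))
  check_C(telo, params$k)
  check_times(t_span)
  rate <- 2^params$k * params$delta_ratio
  theta_star <- theta_steady_state(params, telo)
  theta <- theta_star + (theta0 - theta_star) * exp(-rate * t_span)
  out <- tibble::tibble(time_days = t_span, theta_bp = theta)
  scale <- max(abs(theta_star), 1)
  attr(out, "steady_state") <- theta_star
  attr(out, "rate") <- rate
  attr(out, "converged") <- abs(theta[length(theta)] - theta_star) < 0.01 * scale
  out
}

#' Steady-state telomere difference under the explicit model
#'
#' Applies the one-pool steady-state pattern to each subpopulation: with the
#' stationarity ties, subpopulation i satisfies
#' \eqn{\Theta_i = C\delta + 2\delta (p_{si} - p_n) / (d_{si} - p_{si})}.
#' The measured bulk value is the size-weighted mean of the two, consistent
#' with the label observation model (one sorting gate).
#'
#' @param params An [explicit_params()] object.
#' @param telo A [telomere_params()] object.
#' @return A one-row tibble with `theta_1`, `theta_2`, and the bulk
#'   observable `theta_bp`.
#' @export
theta_explicit <- function(params, telo) {
  stopifnot(inherits(params, "explicit_params"), inherits(telo, "telomere_params"))
  check_C(telo, params$k)
  th <- function(p_s, d_s) {
    telo$C * telo$delta_bp + 2 * telo$delta_bp * (p_s - params$p_n) / (d_s - p_s)
  }
  t1 <- th(params$p_s1, params$d_s1)
  t2 <- th(params$p_s2, params$d_s2)
  w2 <- params$rel_size_slow
  tibble::tibble(theta_1 = t1, theta_2 = t2,
                 theta_bp = (1 - w2) * t1 + w2 * t2)
}

#' Mean-division trajectories of the naive and TSCM pools
#'
#' The mean number of divisions of naive cells grows linearly
#' (\eqn{\dot\mu_{TN} = 2 p_n}) while the TSCM mean relaxes towards the
#' naive mean plus the steady-state offset.  Mostly useful for checking the
#' division-indexed compartment representation.
#'
#' @inheritParams theta_dynamics
#' @return A tibble with columns `time_days`, `mu_TN`, `mu_TSCM`.
#' @export
mean_divisions <- function(params, telo, t_span = seq(0, 3000, by = 10)) {
  th <- theta_dynamics(params, telo, t_span, theta0 = 0)
  mu_tn <- 2 * params$p_n * t_span
  tibble::tibble(time_days = t_span, mu_TN = mu_tn,
                 mu_TSCM = mu_tn + th$theta_bp / telo$delta_bp)
}
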