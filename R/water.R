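#' Body-water label availability parameters
#'
#' Container for the empirical two-phase description of deuterium availability
#' in body water, as measured in saliva.  During label administration
#' (`t <= tau`) enrichment rises from the baseline `beta_s` towards the
#' plateau `f_r` at the body-water turnover rate `delta_w`; after label
#' cessation it washes out exponentially at the same rate:
#' \deqn{U(t) = f_r (1 - e^{-\delta_w t}) + \beta_s e^{-\delta_w t}, \quad t \le \tau}
#' \deqn{U(t) = U(\tau)\, e^{-\delta_w (t - \tau)}, \quad t > \tau}
#'
#' @param f_r Plateau enrichment fraction reached during dosing (0-1).
#' @param delta_w Body-water turnover rate, per day (> 0).
#' @param beta_s Baseline saliva enrichment fraction (0 <= beta_s <= f_r).
#' @param tau Time at which label administration stops, days (> 0).
#'   The 7-week dosing protocol corresponds to the default of 49 days.
#'
#' @return An object of class `body_water_params`.
#' @examples
#' bw <- body_water_params(f_r = 0.05, delta_w = 0.1, beta_s = 0.01)
#' water_enrichment(c(0, 10, 49, 100), bw)
#' @export
body_water_params <- function(f_r, delta_w, beta_s = 0, tau = 49) {
  stopifnot(is.numeric(f_r), is.numeric(delta_w), is.numeric(beta_s), is.numeric(tau))
  if (f_r < 0 || f_r > 1) abort("`f_r` must lie in [0, 1].")
  if (beta_s < 0 || beta_s > f_r) abort("`beta_s` must lie in [0, f_r].")
  if (delta_w <= 0) abort("`delta_w` must be > 0.")
  if (tau <= 0) abort("`tau` must be > 0.")
  structure(
    list(f_r = f_r, delta_w = delta_w, beta_s = beta_s, tau = tau),
    class = "body_water_params"
  )
}

#' @export
print.body_water_params <- function(x, ...) {
  cat("Body-water label availability U(t)\n")
  cat(sprintf("  f_r = %.4g  delta_w = %.4g /d  beta_s = %.4g  tau = %g d\n",
              x$f_r, x$delta_w, x$beta_s, x$tau))
  invisible(x)
}

#' Evaluate body-water enrichment U(t)
#'
#' @param t Times in days since label start (non-negative).
#' @param params A [body_water_params()] object.
#' @return Numeric vector of enrichment fractions, continuous at `t = tau`.
#' @export
water_enrichment <- function(t, params) {
  stopifnot(inherits(params, "body_water_params"))
  if (any(t < 0)) abort("`t` must be non-negative.")
  pes_eval(water_pes(params), t)
}

# U(t) as a piecewise exponential sum (internal; consumed by the label solver).
water_pes <- function(params) {
  f_r <- params$f_r; dw <- params$delta_w; b <- params$beta_s; tau <- params$tau
  up <- es_new(c(f_r, b - f_r), c(0, -dw))                    # uptake phase
  u_tau <- es_eval(up, tau)
  down <- es_new(u_tau * exp(dw * tau), -dw)                  # washout phase
  pes_new(breaks = c(0, tau), pieces = list(up, down))
}

#' Fit the body-water enrichment curve to saliva measurements
#'
#' Estimates `f_r`, `delta_w` and `beta_s` by bounded nonlinear least squares
#' with `tau` fixed to the dosing-protocol value.  A small deterministic grid
#' of starting values guards against local minima.
#'
#' @param data A data frame with columns `time_days` and `enrichment`
#'   (and optionally `subject_id`, in which case each subject is fitted
#'   separately).
#' @param tau Label-cessation time in days (fixed, not fitted).
#' @param f_r_max Upper bound for `f_r`; enrichment from a 70% heavy-water
#'   dosing scheme is a few percent, so the default bound is 0.2.
#' @return A tibble with one row per subject: `f_r`, `delta_w`, `beta_s`,
#'   `tau`, residual sum of squares `rss`, number of points `n_points`, and a
#'   `note` column flagging non-identifiable (flat) series.
#' @examples
#' bw <- body_water_params(0.04, 0.08, 0.005)
#' d <- tibble::tibble(time_days = seq(0, 120, length.out = 10),
#'                     enrichment = water_enrichment(time_days, bw))
#' fit_water(d)
#' @export
fit_water <- function(data, tau = 49, f_r_max = 0.2) {
  data <- validate_saliva(data)
  if (!"subject_id" %in% names(data)) data$subject_id <- "s1"
  dplyr::group_by(data, .data$subject_id) |>
    dplyr::group_modify(~ fit_water_one(.x, tau = tau, f_r_max = f_r_max)) |>
    dplyr::ungroup()
}

validate_saliva <- function(data) {
  data <- tibble::as_tibble(data)
  req <- c("time_days", "enrichment")
  miss <- setdiff(req, names(data))
  if (length(miss)) abort(paste0("saliva data lacks column(s): ", paste(miss, collapse = ", ")))
  if (any(data$time_days < 0)) abort("saliva `time_days` must be non-negative.")
  if (any(data$enrichment < 0 | data$enrichment > 1)) {
    abort("saliva `enrichment` must lie in [0, 1].")
  }
  data
}

fit_water_one <- function(d, tau, f_r_max) {
  d <- dplyr::arrange(d, .data$time_days)
  n <- nrow(d)
  if (n < 4L) abort("need at least 4 saliva points to fit 3 free parameters.")
  y <- d$enrichment
  tt <- d$time_days

  resid_fn <- function(par) {
    bw <- body_water_params(
      f_r = par[1], delta_w = par[2],
      beta_s = min(par[3], par[1]), tau = tau
    )
    water_enrichment(tt, bw) - y
  }

  lower <- c(1e-6, 1e-5, 0)
  upper <- c(f_r_max, 1, f_r_max)
  starts <- expand.grid(
    f_r = c(0.3, 0.7) * f_r_max + 1e-4,
    delta_w = c(0.03, 0.1, 0.3),
    beta_s = c(0, 0.01)
  )
  # data-informed start: plateau from late points, baseline from the first
  starts <- rbind(
    starts,
    data.frame(
      f_r = min(max(max(y), 1e-4), f_r_max),
      delta_w = 0.1,
      beta_s = min(max(y[1], 0), f_r_max)
    )
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(as.numeric(starts[i, ]), lower), upper),
      lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("all starts failed in fit_water().")
  p <- best$par
  p[3] <- min(p[3], p[1])
  note <- ""
  if (sd(y) < 1e-10 || p[1] <= lower[1] * 1.01) {
    note <- "non-identifiable: no label uptake detected"
  }
  tibble::tibble(
    f_r = p[1], delta_w = p[2], beta_s = p[3], tau = tau,
    rss = best$deviance, n_points = n, note = note
  )
}

#' Convert a row of water-fit estimates to a parameter object
#'
#' @param fit A one-row data frame as returned by [fit_water()] (or any data
#'   frame with columns `f_r`, `delta_w`, `beta_s`, `tau`).
#' @return A [body_water_params()] object.
#' @export
as_body_water_params <- function(fit) {
  stopifnot(nrow(fit) == 1L)
  body_water_params(fit$f_r, fit$delta_w, fit$beta_s, fit$tau)
}
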