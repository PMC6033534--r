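#' Biexponential decay parameters for vaccine-induced TSCM frequencies
#'
#' Describes the frequency of antigen-specific TSCM cells as a function of
#' time since vaccination as the sum of a fast and a slow exponentially
#' decaying component,
#' \deqn{F(t) = A\,[\,r e^{-\alpha t} + (1 - r) e^{-\beta t}\,],}
#' with time in years.  By convention the fast component is listed first
#' (`alpha >= beta_y`); inputs violating the convention are reordered.
#'
#' @param r Initial weight of the fast component (0-1).
#' @param alpha Fast decay rate, per year (>= 0).
#' @param beta_y Slow decay rate, per year (>= 0).
#' @param A Amplitude: frequency at `t = 0` (fraction of CD8+ CD16-
#'   lymphocytes, > 0).
#' @return An object of class `yfv_params`.
#' @examples
#' yfv_params(r = 0.9, alpha = log(2) / 0.4, beta_y = log(2) / 9, A = 1e-4)
#' @export
yfv_params <- function(r, alpha, beta_y, A = 1) {
  stopifnot(r >= 0, r <= 1, alpha >= 0, beta_y >= 0, A > 0)
  if (alpha < beta_y) {
    tmp <- alpha; alpha <- beta_y; beta_y <- tmp
    r <- 1 - r
  }
  structure(list(r = r, alpha = alpha, beta_y = beta_y, A = A),
            class = "yfv_params")
}

#' @export
print.yfv_params <- function(x, ...) {
  cat("Biexponential vaccine-decay model\n")
  cat(sprintf("  A = %.4g  r = %.4g  alpha = %.4g /y  beta = %.4g /y\n",
              x$A, x$r, x$alpha, x$beta_y))
  cat(sprintf("  component half-lives: %.3g y (fast), %.3g y (slow)\n",
              log(2) / x$alpha, log(2) / x$beta_y))
  invisible(x)
}

#' Predicted antigen-specific TSCM frequency
#'
#' @param t_years Time since vaccination in years (>= 0).
#' @param params A [yfv_params()] object.
#' @return Numeric vector of frequencies.
#' @export
yfv_frequency <- function(t_years, params) {
  stopifnot(inherits(params, "yfv_params"))
  if (any(t_years < 0)) abort("`t_years` must be non-negative.")
  params$A * (params$r * exp(-params$alpha * t_years) +
                (1 - params$r) * exp(-params$beta_y * t_years))
}

#' Map explicit-model kinetics to vaccine-decay parameters
#'
#' Each vaccine-induced clone is assumed to split like a naive-derived
#' clonal burst: a fraction `1 - f` seeds the fast subpopulation, decaying
#' at its clonal net-loss rate `d_s1 - p_s1`, and a fraction `f` seeds the
#' slow one.  This gives `r` = `1 - f`, `alpha = (d_s1 - p_s1) * 365.25` and
#' `beta_y = (d_s2 - p_s2) * 365.25` per year.  The linkage function can be
#' replaced for sensitivity analyses.
#'
#' @param params An [explicit_params()] object.
#' @param A Amplitude (initial frequency) for the cohort; free, as it
#'   depends on the vaccine dose and precursor frequency rather than on
#'   TSCM kinetics.
#' @param linkage A function `(params, A) -> yfv_params`; the default
#'   implements the burst-split mapping described above.
#' @return A [yfv_params()] object.
#' @export
link_explicit_to_yfv <- function(params, A = 1, linkage = NULL) {
  stopifnot(inherits(params, "explicit_params"))
  if (is.null(linkage)) {
    yfv_params(r = 1 - params$f,
               alpha = (params$d_s1 - params$p_s1) * DAYS_PER_YEAR,
               beta_y = (params$d_s2 - params$p_s2) * DAYS_PER_YEAR,
               A = A)
  } else {
    linkage(params, A)
  }
}

#' Fit the biexponential decay model to a cross-sectional vaccine cohort
#'
#' Least squares on `log10(frequency)`, since observations span orders of
#' magnitude over decades; observations at or below the detection limit are
#' treated as left-censored (they contribute a residual only when the
#' prediction exceeds the limit).
#'
#' @param data A data frame with columns `years_post_vaccination` and
#'   `frequency`.
#' @param detection_limit Optional frequency below which observations are
#'   considered censored.
#' @param n_starts Number of random multi-starts (seeded internally from the
#'   current RNG state).
#' @return A list with elements `params` (a [yfv_params()] object), `rss`
#'   (on the log10 scale) and `n_points`.
#' @export
fit_yfv <- function(data, detection_limit = NULL, n_starts = 20) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("years_post_vaccination", "frequency") %in% names(data)))
  tt <- data$years_post_vaccination
  yy <- data$frequency
  resid_fn <- function(th) {
    pars <- yfv_params(r = plogis_(th[1]), alpha = 10^th[2],
                       beta_y = min(10^th[3], 10^th[2]), A = 10^th[4])
    yfv_log_residuals(pars, tt, yy, detection_limit)
  }
  lower <- c(-8, -2, -3, log10(max(min(yy[yy > 0], 1e-8), 1e-10)) - 2)
  upper <- c(8, 2, 1, 0)
  starts <- matrix(runif(4 * n_starts, rep(lower, each = n_starts),
                         rep(upper, each = n_starts)), ncol = 4)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(par = starts[i, ], lower = lower,
                                  upper = upper, fn = resid_fn,
                                  control = minpack.lm::nls.lm.control(maxiter = 300)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("all starts failed in fit_yfv().")
  th <- best$par
  list(
    params = yfv_params(r = plogis_(th[1]), alpha = 10^th[2],
                        beta_y = min(10^th[3], 10^th[2]), A = 10^th[4]),
    rss = best$deviance,
    n_points = length(tt)
  )
}

plogis_ <- function(x) 1 / (1 + exp(-x))
qlogis_ <- function(p) log(p / (1 - p))

# log10-scale residuals with optional left-censoring at the detection limit
yfv_log_residuals <- function(params, t_years, freq, detection_limit = NULL) {
  pred <- yfv_frequency(t_years, params)
  floor_ <- if (is.null(detection_limit)) 1e-12 else detection_limit
  obs <- pmax(freq, floor_)
  pred <- pmax(pred, 1e-300)
  r <- log10(pred) - log10(obs)
  if (!is.null(detection_limit)) {
    cens <- freq <= detection_limit
    r[cens] <- pmax(r[cens], 0)   # no penalty for predicting below the limit
  }
  r
}
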