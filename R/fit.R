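#' Fitting configuration
#'
#' Controls which model variant is fitted, which datasets enter the combined
#' objective, how datasets are weighted, and how the multi-start optimiser
#' behaves.
#'
#' @param variant One of `"homogeneous"`, `"implicit"`, `"explicit"`.
#' @param datasets Character subset of `c("label", "telomere", "yfv")`.
#'   The vaccine dataset requires the explicit variant.
#' @param weighting Weighting strategy for combining per-dataset sums of
#'   squared residuals: `"sigma"` (default; each residual divided by its
#'   dataset's measurement scale, so weighted residuals share a common unit
#'   variance and nested F-tests stay calibrated), `"variance"` (per-dataset
#'   SSR divided by `n_i * sigma_i^2`), `"equal"`, `"count"` (divide by
#'   `n_i`), `"telomere_up"` or `"vaccine_up"` (sigma weights with the named
#'   dataset upweighted fivefold).
#' @param k Clonal-burst divisions (integer 0-20), fixed for a single fit;
#'   [k_scan()] loops over a range.
#' @param C_mode Telomerase compensation handling: `"free"` (fitted in
#'   `[0, k]`), `"zero"` (full compensation) or `"max"` (`C = k`, none).
#' @param n_starts Number of Latin-hypercube starting points for the global
#'   stage; each is polished by bounded Levenberg-Marquardt least squares.
#' @param seed Integer seed for the start draw (fits are reproducible given
#'   `seed` and config).
#' @param sigma Named list of assumed measurement scales used by the
#'   variance weighting: `label` (fraction units), `telomere` (bp; a
#'   per-observation `sd_bp` column takes precedence), `yfv` (log10 units).
#' @param bounds Named list of `c(lower, upper)` overrides on the natural
#'   scale for any of: `p_n`, `p_s`, `delta_ratio`, `ds_star`, `p_s1`,
#'   `net_loss1`, `p_s2`, `net_loss2`, `f`, `c`, `A`, `dn_loss`.
#' @param fit_c If `TRUE`, the enrichment amplification factor `c` is
#'   estimated (bounds `bounds$c`).  By default it is held at `c_value`:
#'   `c` multiplies the water curve `U(t)` wherever it appears, so with a
#'   free `c` the label-curve amplitude is unidentifiable from a 7-week
#'   protocol and the homogeneity constraint loses its testable content.
#' @param c_value Value of `c` when not fitted (default 1: enrichment
#'   amplification treated as known subject-level chemistry folded into the
#'   measured water curve).
#' @param naive_heterogeneity If `TRUE`, the loss rate of labelled naive DNA
#'   is freed from its homogeneous value `p_n` (adds one parameter).
#' @param detection_limit Optional left-censoring limit for vaccine
#'   frequencies.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(variant = c("implicit", "homogeneous", "explicit"),
                       datasets = c("label", "telomere"),
                       weighting = c("sigma", "variance", "equal", "count",
                                     "telomere_up", "vaccine_up"),
                       k = 2, C_mode = c("free", "zero", "max"),
                       n_starts = 50, seed = 1,
                       sigma = list(label = 5e-4, telomere = 150, yfv = 0.3),
                       bounds = list(), fit_c = FALSE, c_value = 1,
                       naive_heterogeneity = FALSE,
                       detection_limit = NULL, maxiter = 200) {
  variant <- match.arg(variant)
  weighting <- match.arg(weighting)
  C_mode <- match.arg(C_mode)
  if (!length(datasets)) abort("at least one dataset must be selected.")
  datasets <- match.arg(datasets, c("label", "telomere", "yfv"),
                        several.ok = TRUE)
  if ("yfv" %in% datasets && variant != "explicit") {
    abort("the vaccine dataset can only inform the explicit variant.")
  }
  check_k(k)
  sig <- list(label = 5e-4, telomere = 150, yfv = 0.3)
  sig[names(sigma)] <- sigma
  structure(
    list(variant = variant, datasets = datasets, weighting = weighting,
         k = k, C_mode = C_mode, n_starts = n_starts, seed = seed,
         sigma = sig, bounds = bounds, fit_c = fit_c, c_value = c_value,
         naive_heterogeneity = naive_heterogeneity,
         detection_limit = detection_limit, maxiter = maxiter),
    class = "fit_config"
  )
}

# ---- data bundle -------------------------------------------------------------

#' Bundle one subject's datasets for fitting
#'
#' @param water A [body_water_params()] object (typically from
#'   [fit_water()] on the subject's saliva series).
#' @param label Tibble with columns `population` (`"naive"` / `"tscm"`),
#'   `time_days`, `fraction_labelled`, or `NULL`.
#' @param telomere One-row tibble with `theta_bp` (and optionally `sd_bp`),
#'   or `NULL`.
#' @param yfv Tibble with `years_post_vaccination`, `frequency`, or `NULL`.
#' @return An object of class `fit_data`.
#' @export
fit_data <- function(water, label = NULL, telomere = NULL, yfv = NULL) {
  stopifnot(inherits(water, "body_water_params"))
  if (!is.null(label)) {
    label <- tibble::as_tibble(label)
    stopifnot(all(c("population", "time_days", "fraction_labelled") %in% names(label)))
    check_times(sort(label$time_days))
    if (!all(label$population %in% c("naive", "tscm"))) {
      abort("label `population` must be 'naive' or 'tscm'.")
    }
  }
  if (!is.null(telomere)) {
    telomere <- tibble::as_tibble(telomere)
    stopifnot("theta_bp" %in% names(telomere), nrow(telomere) == 1L)
  }
  if (!is.null(yfv)) {
    yfv <- tibble::as_tibble(yfv)
    stopifnot(all(c("years_post_vaccination", "frequency") %in% names(yfv)))
  }
  structure(list(water = water, label = label, telomere = telomere, yfv = yfv),
            class = "fit_data")
}

dataset_sizes <- function(data, datasets) {
  n <- c(label = 0L, telomere = 0L, yfv = 0L)
  if ("label" %in% datasets && !is.null(data$label)) n["label"] <- nrow(data$label)
  if ("telomere" %in% datasets && !is.null(data$telomere)) n["telomere"] <- 1L
  if ("yfv" %in% datasets && !is.null(data$yfv)) n["yfv"] <- nrow(data$yfv)
  n
}

dataset_weights <- function(data, config) {
  n <- dataset_sizes(data, config$datasets)
  sd_bp <- if (!is.null(data$telomere) && "sd_bp" %in% names(data$telomere)) {
    data$telomere$sd_bp[1]
  } else NULL
  sig <- c(label = config$sigma$label,
           telomere = if (!is.null(sd_bp) && is.finite(sd_bp) && sd_bp > 0)
             sd_bp else config$sigma$telomere,
           yfv = config$sigma$yfv)
  w <- switch(config$weighting,
    equal = c(label = 1, telomere = 1, yfv = 1),
    count = ifelse(n > 0, 1 / pmax(n, 1), 0),
    variance = 1 / (pmax(n, 1) * sig^2),
    sigma = ,
    telomere_up = ,
    vaccine_up = 1 / sig^2
  )
  names(w) <- names(n)
  if (config$weighting == "telomere_up") w["telomere"] <- 5 * w["telomere"]
  if (config$weighting == "vaccine_up") w["yfv"] <- 5 * w["yfv"]
  w[n == 0] <- 0
  w
}

# ---- residuals and SSR -------------------------------------------------------

label_predictions <- function(kinetics, water, label) {
  tt <- sort(unique(label$time_days))
  pred <- if (inherits(kinetics, "implicit_params")) {
    label_curves_implicit_(kinetics, water, tt)
  } else {
    label_curves_explicit_(kinetics, water, tt)
  }
  idx <- match(label$time_days, tt)
  ifelse(label$population == "naive", pred$F_TN[idx], pred$F_TSCM[idx])
}

theta_prediction <- function(kinetics, telo) {
  d <- telo$delta_bp
  if (inherits(kinetics, "implicit_params")) {
    if (kinetics$delta_ratio <= 0) return(NA_real_)
    telo$C * d + (kinetics$p_s - kinetics$p_n) * d /
      (2^(kinetics$k - 1) * kinetics$delta_ratio)
  } else {
    t1 <- telo$C * d + 2 * d * (kinetics$p_s1 - kinetics$p_n) /
      (kinetics$d_s1 - kinetics$p_s1)
    t2 <- telo$C * d + 2 * d * (kinetics$p_s2 - kinetics$p_n) /
      (kinetics$d_s2 - kinetics$p_s2)
    w2 <- kinetics$rel_size_slow
    (1 - w2) * t1 + w2 * t2
  }
}

resid_components <- function(kinetics, telo, yfv_pars, data, config) {
  out <- list()
  if ("label" %in% config$datasets && !is.null(data$label)) {
    out$label <- label_predictions(kinetics, data$water, data$label) -
      data$label$fraction_labelled
  }
  if ("telomere" %in% config$datasets && !is.null(data$telomere)) {
    out$telomere <- theta_prediction(kinetics, telo) - data$telomere$theta_bp[1]
  }
  if ("yfv" %in% config$datasets && !is.null(data$yfv)) {
    out$yfv <- yfv_log_residuals(yfv_pars, data$yfv$years_post_vaccination,
                                 data$yfv$frequency, config$detection_limit)
  }
  out
}

#' Combined weighted sum of squared residuals
#'
#' Label residuals are taken on the natural (fraction) scale, the telomere
#' residual on the base-pair scale, and vaccine residuals on the log10
#' frequency scale; the per-dataset sums are combined with the configured
#' weighting strategy.
#'
#' @param data A [fit_data()] bundle.
#' @param kinetics An [implicit_params()] or [explicit_params()] object.
#' @param telo A [telomere_params()] object (needed when the telomere
#'   dataset is included).
#' @param yfv_pars A [yfv_params()] object (needed when the vaccine dataset
#'   is included).
#' @param config A [fit_config()] object; its `datasets` and `weighting`
#'   fields control the combination.
#' @return A list with `total` and the per-dataset components (unweighted
#'   SSRs) plus the weights used.
#' @export
combined_ssr <- function(data, kinetics, telo = NULL, yfv_pars = NULL,
                         config = fit_config()) {
  stopifnot(inherits(data, "fit_data"))
  r <- resid_components(kinetics, telo, yfv_pars, data, config)
  w <- dataset_weights(data, config)
  comp <- vapply(r, function(x) sum(x^2), numeric(1))
  total <- sum(w[names(comp)] * comp)
  list(total = total, components = comp, weights = w[names(comp)])
}

# ---- parameterisation --------------------------------------------------------

default_bounds <- function() {
  list(
    p_n = c(1e-6, 0.05), p_s = c(1e-6, 0.3), delta_ratio = c(1e-10, 0.5),
    ds_star = c(1e-5, 1), p_s1 = c(1e-6, 0.3), p_s2 = c(1e-6, 0.3),
    net_loss1 = c(log(2) / (60 * DAYS_PER_YEAR), 0.5),
    net_loss2 = c(log(2) / (60 * DAYS_PER_YEAR), 0.5),
    f = c(1e-5, 1 - 1e-5), c = c(0.5, 6), A = c(1e-8, 1e-2),
    dn_loss = c(1e-6, 0.2)
  )
}

# Parameter table: name, transform, bounds on the optimiser scale.
# Rates and amplitudes are fitted on log10 scale (magnitudes span 1e-5..1e-1
# per day); fractions on the logit scale; c and C linearly.
build_parameterization <- function(config, data) {
  b <- default_bounds()
  b[names(config$bounds)] <- config$bounds
  use_telo <- "telomere" %in% config$datasets && !is.null(data$telomere)
  use_yfv <- "yfv" %in% config$datasets && !is.null(data$yfv)
  row <- function(name, transform, lo, hi) {
    tibble::tibble(name = name, transform = transform, lower = lo, upper = hi)
  }
  tr <- function(name) {
    lo <- b[[name]][1]; hi <- b[[name]][2]
    row(name, "log10", log10(lo), log10(hi))
  }
  lg <- function(name) {
    lo <- b[[name]][1]; hi <- b[[name]][2]
    row(name, "logit", qlogis_(lo), qlogis_(hi))
  }
  tab <- tr("p_n")
  if (config$variant == "explicit") {
    tab <- dplyr::bind_rows(tab, lg("f"), tr("p_s1"), tr("net_loss1"),
                            tr("p_s2"), tr("net_loss2"))
  } else {
    tab <- dplyr::bind_rows(tab, tr("p_s"), tr("delta_ratio"))
    if (config$variant == "implicit") tab <- dplyr::bind_rows(tab, tr("ds_star"))
  }
  if (config$fit_c) {
    tab <- dplyr::bind_rows(tab, row("c", "identity", b$c[1], b$c[2]))
  }
  if (config$naive_heterogeneity) tab <- dplyr::bind_rows(tab, tr("dn_loss"))
  if (use_telo && config$C_mode == "free" && config$k > 0) {
    tab <- dplyr::bind_rows(tab, row("C", "identity", 0, config$k))
  }
  if (use_yfv) tab <- dplyr::bind_rows(tab, tr("A"))
  tab
}

untransform <- function(th, tab) {
  val <- numeric(length(th))
  for (i in seq_along(th)) {
    val[i] <- switch(tab$transform[i],
      log10 = 10^th[i],
      logit = plogis_(th[i]),
      identity = th[i]
    )
  }
  setNames(val, tab$name)
}

params_from_vector <- function(v, config) {
  c_val <- if ("c" %in% names(v)) v[["c"]] else config$c_value
  C_val <- switch(config$C_mode,
                  free = if ("C" %in% names(v)) v[["C"]] else 0,
                  zero = 0, max = config$k)
  telo <- telomere_params(delta_bp = 50, C = C_val)
  dn_loss <- if (config$naive_heterogeneity) v[["dn_loss"]] else NULL
  if (config$variant == "explicit") {
    kin <- explicit_params(
      p_n = v[["p_n"]], f = v[["f"]],
      p_s1 = v[["p_s1"]], d_s1 = v[["p_s1"]] + v[["net_loss1"]],
      p_s2 = v[["p_s2"]], d_s2 = v[["p_s2"]] + v[["net_loss2"]],
      k = config$k, c = c_val, dn_loss = dn_loss
    )
    yfv <- if ("A" %in% names(v)) {
      link_explicit_to_yfv(kin, A = v[["A"]])
    } else NULL
  } else {
    kin <- implicit_params(
      p_n = v[["p_n"]], p_s = v[["p_s"]], delta_ratio = v[["delta_ratio"]],
      k = config$k, c = c_val,
      ds_star = if (config$variant == "implicit") v[["ds_star"]] else NULL,
      dn_loss = dn_loss
    )
    yfv <- NULL
  }
  list(kinetics = kin, telo = telo, yfv = yfv)
}

weighted_residuals <- function(th, tab, data, config, sqrt_w) {
  v <- untransform(th, tab)
  mod <- params_from_vector(v, config)
  r <- resid_components(mod$kinetics, mod$telo, mod$yfv, data, config)
  unlist(lapply(names(r), function(nm) r[[nm]] * sqrt_w[[nm]]), use.names = FALSE)
}

# ---- fit_model ---------------------------------------------------------------

#' Fit a label/telomere/vaccine model by multi-start least squares
#'
#' Global-then-local optimisation: `n_starts` Latin-hypercube points over the
#' (transformed) parameter box, each polished by bounded
#' Levenberg-Marquardt least squares; the best final objective wins.  All
#' starts are logged so multimodality is visible.  Equal-objective ties
#' (relative 1e-8) are broken in favour of the lowest slow-subpopulation
#' disappearance rate, then lexicographic parameter order.  For the explicit
#' variant the subpopulations are relabelled so that subpopulation 1 is the
#' faster one (shorter clonal half-life).
#'
#' @param data A [fit_data()] bundle.
#' @param config A [fit_config()] object.
#' @param extra_starts Optional list of named parameter vectors (natural
#'   scale, as in the fit's `estimates`) appended to the random starts;
#'   used e.g. to seed a nested model's optimum.
#' @return An object of class `tscm_fit`: point estimates, per-dataset SSR,
#'   derived quantities, and the per-start convergence log.  Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @export
fit_model <- function(data, config, extra_starts = list()) {
  stopifnot(inherits(data, "fit_data"), inherits(config, "fit_config"))
  if ("label" %in% config$datasets && is.null(data$label)) {
    abort("config requests the label dataset but `data$label` is missing.")
  }
  if ("yfv" %in% config$datasets && is.null(data$yfv)) {
    abort("config requests the vaccine dataset but `data$yfv` is missing.")
  }
  if ("telomere" %in% config$datasets && is.null(data$telomere)) {
    abort("config requests the telomere dataset but `data$telomere` is missing.")
  }
  tab <- build_parameterization(config, data)
  npar <- nrow(tab)
  n_points <- sum(dataset_sizes(data, config$datasets))
  if (n_points <= npar) {
    abort(sprintf("insufficient data: %d points for %d free parameters.",
                  n_points, npar))
  }
  w <- dataset_weights(data, config)
  sqrt_w <- lapply(as.list(w), sqrt)

  # seed only the start draw, without clobbering the caller's RNG stream
  starts <- if (config$n_starts > 0) {
    grid <- withr::with_seed(config$seed, lhs::randomLHS(config$n_starts, npar))
    t(t(grid) * (tab$upper - tab$lower) + tab$lower)
  } else {
    if (!length(extra_starts)) abort("`n_starts` = 0 requires `extra_starts`.")
    matrix(numeric(0), ncol = npar)
  }
  if (length(extra_starts)) {
    extra <- t(vapply(extra_starts, function(v) transform_vector(v, tab),
                      numeric(npar)))
    starts <- rbind(starts, extra)
  }

  log_rows <- vector("list", nrow(starts))
  results <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(starts[i, ], tab$lower), tab$upper),
      lower = tab$lower, upper = tab$upper,
      fn = weighted_residuals, tab = tab, data = data, config = config,
      sqrt_w = sqrt_w,
      control = minpack.lm::nls.lm.control(maxiter = config$maxiter)
    ), silent = TRUE)
    ok <- !inherits(fit, "try-error")
    log_rows[[i]] <- tibble::tibble(
      start = i, converged = ok,
      ssr = if (ok) fit$deviance else NA_real_,
      info = if (ok) fit$info else NA_integer_,
      message = if (ok) fit$message else as.character(fit)
    )
    results[[i]] <- if (ok) fit else NULL
  }
  start_log <- dplyr::bind_rows(log_rows)
  if (all(!start_log$converged)) {
    abort("all optimiser starts failed; see the start log for diagnostics.")
  }

  best_idx <- pick_best_start(results, tab, config)
  best <- results[[best_idx]]
  v <- untransform(best$par, tab)
  v <- canonicalize_estimates(v, config)
  mod <- params_from_vector(v, config)
  ssr <- combined_ssr(data, mod$kinetics, mod$telo, mod$yfv, config)

  structure(
    list(config = config, data = data, parameterization = tab,
         estimates = v, kinetics = mod$kinetics, telo = mod$telo,
         yfv = mod$yfv, ssr = ssr$total, ssr_components = ssr$components,
         weights = ssr$weights, n_points = n_points, n_par = npar,
         start_log = start_log, best_start = best_idx,
         derived = derived_quantities_(mod$kinetics, config)),
    class = "tscm_fit"
  )
}

transform_vector <- function(v, tab) {
  th <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    x <- v[[tab$name[i]]]
    th[i] <- switch(tab$transform[i],
                    log10 = log10(x), logit = qlogis_(x), identity = x)
  }
  pmin(pmax(th, tab$lower), tab$upper)
}

pick_best_start <- function(results, tab, config) {
  ssrs <- vapply(results, function(r) if (is.null(r)) Inf else r$deviance,
                 numeric(1))
  best <- min(ssrs)
  cand <- which(ssrs <= best * (1 + 1e-8) + 1e-300)
  if (length(cand) == 1L) return(cand)
  # tie-break: lowest slow-subpopulation disappearance rate, then lexicographic
  key <- lapply(cand, function(i) {
    v <- untransform(results[[i]]$par, tab)
    d_s2 <- if (config$variant == "explicit") {
      min(v[["p_s1"]] + v[["net_loss1"]], v[["p_s2"]] + v[["net_loss2"]])
    } else 0
    c(d_s2, unname(v))
  })
  ord <- do.call(order, as.data.frame(t(vapply(key, identity, key[[1]]))))
  cand[ord[1]]
}

canonicalize_estimates <- function(v, config) {
  if (config$variant != "explicit") return(v)
  if (v[["net_loss1"]] < v[["net_loss2"]]) {
    tmp <- v[c("p_s1", "net_loss1")]
    v[c("p_s1", "net_loss1")] <- v[c("p_s2", "net_loss2")]
    v[c("p_s2", "net_loss2")] <- tmp
    v[["f"]] <- 1 - v[["f"]]
  }
  v
}

derived_quantities_ <- function(kin, config) {
  if (inherits(kin, "explicit_params")) {
    tibble::tibble(
      half_life_fast_years = clonal_half_life(kin$d_s1, kin$p_s1) / DAYS_PER_YEAR,
      half_life_slow_years = clonal_half_life(kin$d_s2, kin$p_s2) / DAYS_PER_YEAR,
      rel_size_slow = kin$rel_size_slow,
      fraction_from_naive = {
        w2 <- kin$rel_size_slow; w1 <- 1 - w2
        nl <- w1 * (kin$d_s1 - kin$p_s1) + w2 * (kin$d_s2 - kin$p_s2)
        tot <- nl + w1 * kin$p_s1 + w2 * kin$p_s2
        nl / tot
      },
      self_renewal_slow_days = degree_of_self_renewal(kin, "slow")
    )
  } else {
    br <- derived_bulk_rates(kin)
    tibble::tibble(
      half_life_years = clonal_half_life(kin$d_s, kin$p_s) / DAYS_PER_YEAR,
      fraction_from_naive = br$fraction_from_naive,
      fraction_self_renewal = br$fraction_self_renewal,
      replacement_rate_per_day = br$replacement_rate,
      ds_star_per_day = kin$ds_star
    )
  }
}

#' @export
print.tscm_fit <- function(x, ...) {
  cat(sprintf("tscm_fit: %s variant, datasets: %s\n", x$config$variant,
              paste(x$config$datasets, collapse = "+")))
  cat(sprintf("  k = %d, SSR = %.6g (%d points, %d parameters, %d starts)\n",
              as.integer(x$config$k), x$ssr, x$n_points, x$n_par,
              nrow(x$start_log)))
  est <- x$estimates
  cat("  estimates:", paste(sprintf("%s=%.4g", names(est), est), collapse = "  "), "\n")
  invisible(x)
}

# ---- nested-model statistics -------------------------------------------------

#' F-test for nested least-squares models
#'
#' \deqn{F = \frac{(SSR_r - SSR_f)/(p_f - p_r)}{SSR_f/(n - p_f)}}
#' with p-value from the upper tail of the F distribution with
#' `(p_f - p_r, n - p_f)` degrees of freedom.
#'
#' @param ssr_reduced,ssr_full Sums of squared residuals at the optima of
#'   the reduced and full model (`ssr_reduced >= ssr_full >= 0`).
#' @param n_points Number of data points.
#' @param p_reduced,p_full Numbers of free parameters (`p_full > p_reduced`,
#'   `n_points > p_full`).
#' @return A one-row tibble with `F`, `df1`, `df2`, `p_value`.
#' @examples
#' f_test_nested(2, 1, n_points = 20, p_reduced = 4, p_full = 5)
#' @export
f_test_nested <- function(ssr_reduced, ssr_full, n_points, p_reduced, p_full) {
  if (ssr_full < 0 || ssr_reduced < ssr_full * (1 - 1e-12)) {
    abort("requires `ssr_reduced >= ssr_full >= 0` (optima of nested models).")
  }
  if (p_full <= p_reduced) abort("`p_full` must exceed `p_reduced`.")
  if (n_points <= p_full) abort("`n_points` must exceed `p_full`.")
  df1 <- p_full - p_reduced
  df2 <- n_points - p_full
  Fstat <- max(0, (ssr_reduced - ssr_full) / df1 / (ssr_full / df2))
  tibble::tibble(F = Fstat, df1 = df1, df2 = df2,
                 p_value = pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Test kinetic homogeneity of the TSCM pool
#'
#' Fits the homogeneous model (labelled-DNA disappearance constrained to the
#' bulk replacement rate) and the implicit-heterogeneity model (constraint
#' relaxed; one extra parameter), and compares them with the nested F-test.
#' The full model's starts include the reduced optimum, which guarantees the
#' nesting inequality `SSR_homogeneous >= SSR_implicit` at the returned
#' optima.
#'
#' @param data A [fit_data()] bundle.
#' @param config A [fit_config()] object; its `variant` field is ignored.
#' @return A list with `fit_reduced`, `fit_full` and `test` (the
#'   [f_test_nested()] row).
#' @export
test_homogeneity <- function(data, config = fit_config()) {
  cfg_h <- config; cfg_h$variant <- "homogeneous"
  cfg_i <- config; cfg_i$variant <- "implicit"
  fit_h <- fit_model(data, cfg_h)
  seed_start <- c(as.list(fit_h$estimates),
                  list(ds_star = fit_h$kinetics$ds_star))
  fit_i <- fit_model(data, cfg_i, extra_starts = list(seed_start))
  test <- f_test_nested(fit_h$ssr, min(fit_i$ssr, fit_h$ssr),
                        n_points = fit_h$n_points,
                        p_reduced = fit_h$n_par, p_full = fit_i$n_par)
  list(fit_reduced = fit_h, fit_full = fit_i, test = test)
}

#' Pool p-values across datasets
#'
#' Fisher's combination: \eqn{X = -2 \sum \ln p_i \sim \chi^2(2m)} under the
#' global null.  The median p-value is reported alongside.
#'
#' @param p_list Numeric vector of p-values in (0, 1].
#' @return A one-row tibble with `n`, `median_p`, `statistic`, `pooled_p`.
#' @examples
#' pool_pvalues(c(0.5, 0.5))
#' @export
pool_pvalues <- function(p_list) {
  p <- as.numeric(p_list)
  if (!length(p)) abort("`p_list` must not be empty.")
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1].")
  X <- -2 * sum(log(p))
  tibble::tibble(n = length(p), median_p = median(p), statistic = X,
                 pooled_p = pchisq(X, df = 2 * length(p), lower.tail = FALSE))
}

#' Scan the clonal-expansion size k
#'
#' Refits the model for each value of `k`, holding everything else in the
#' config fixed, and tabulates the objective together with the derived
#' quantities (self-renewal fraction, clonal half-life, and the expected
#' antigen-specific precursor lifespan under the bulk-pool convention,
#' `Delta = 1e-5`, `f = 1`).
#'
#' @param data A [fit_data()] bundle.
#' @param config A [fit_config()] object (its `k` is ignored).
#' @param k_values Integer values to scan (default 0:20).
#' @return A tibble of class `tscm_kscan`, one row per `k`, with the fits in
#'   the `fit` list-column.
#' @export
k_scan <- function(data, config = fit_config(), k_values = 0:20) {
  rows <- purrr::map(k_values, function(kk) {
    cfg <- config; cfg$k <- kk
    fit <- fit_model(data, cfg)
    kin <- fit$kinetics
    if (inherits(kin, "implicit_params")) {
      hl_days <- clonal_half_life(kin$d_s, kin$p_s)
      frac_self <- derived_bulk_rates(kin)$fraction_self_renewal
      d <- kin$d_s; p <- kin$p_s
    } else {
      hl_days <- clonal_half_life(kin$d_s2, kin$p_s2)
      frac_self <- 1 - fit$derived$fraction_from_naive
      d <- kin$d_s2; p <- kin$p_s2
    }
    n0 <- initial_clone_size(kk, Delta = 1e-5, f = 1)
    tibble::tibble(
      k = kk, ssr = fit$ssr,
      fraction_self_renewal = frac_self,
      half_life_years = hl_days / DAYS_PER_YEAR,
      precursor_lifespan_days = expected_precursor_lifespan(d, p, n0),
      fit = list(fit)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tscm_kscan", class(out))
  out
}

#' Expected antigen-specific precursor lifespan (asymptotic)
#'
#' For a subcritical birth-death clone of initial size `n0`, each founding
#' cell's family survives to time `t` with probability asymptotically
#' `(1 - p/d) exp(-(d - p) t)`; the expected time until the last of `n0`
#' independent families dies is then approximately
#' \deqn{E[T] \approx \frac{\ln(n_0 (1 - p/d)) + \gamma}{d - p},}
#' the extreme-value limit for the maximum of `n0` such lifetimes.  Checked
#' against Gillespie simulation in the package tests.
#'
#' @param d,p Disappearance and proliferation rates, per day (`d > p`).
#' @param n0 Initial clone size (cells).
#' @return Expected extinction time in days (0 when `n0 = 0`).
#' @export
expected_precursor_lifespan <- function(d, p, n0) {
  if (n0 <= 0) return(0)
  if (d <= p) return(Inf)
  gamma_e <- 0.5772156649015329
  arg <- pmax(n0 * (1 - p / d), 1.0000001)
  (log(arg) + gamma_e) / (d - p)
}

#' Constrained fit: is a long slow half-life compatible with the data?
#'
#' Fits the explicit model with the slow subpopulation's net loss rate
#' bounded so that its clonal half-life lies in
#' `[min_halflife_years, max_halflife_years]`, and compares the constrained
#' optimum with the unconstrained one by F-test (the constraint is treated
#' as removing one free parameter).  A non-significant difference means the
#' data are compatible with the imposed half-life range.
#'
#' @param data A [fit_data()] bundle.
#' @param config A [fit_config()] with `variant = "explicit"`.
#' @param min_halflife_years,max_halflife_years Allowed half-life range for
#'   the slow subpopulation, years.
#' @return A list with `fit_unconstrained`, `fit_constrained`, `test` and
#'   the logical `compatible` (p > 0.05).
#' @export
constrained_fit <- function(data, config, min_halflife_years = 5,
                            max_halflife_years = 15) {
  stopifnot(config$variant == "explicit")
  fit_u <- fit_model(data, config)
  cfg_c <- config
  cfg_c$bounds$net_loss2 <- c(net_loss_from_half_life(max_halflife_years),
                              net_loss_from_half_life(min_halflife_years))
  extra <- list()
  hl_u <- fit_u$derived$half_life_slow_years
  if (hl_u >= min_halflife_years && hl_u <= max_halflife_years) {
    extra <- list(as.list(fit_u$estimates))
  }
  fit_c <- fit_model(data, cfg_c, extra_starts = extra)
  ssr_c <- max(fit_c$ssr, fit_u$ssr)
  test <- f_test_nested(ssr_c, fit_u$ssr, n_points = fit_u$n_points,
                        p_reduced = fit_u$n_par - 1, p_full = fit_u$n_par)
  list(fit_unconstrained = fit_u, fit_constrained = fit_c, test = test,
       compatible = test$p_value > 0.05)
}

# ---- confidence intervals ----------------------------------------------------

#' Confidence intervals for fitted and derived quantities
#'
#' Default: parametric bootstrap.  Residual noise is re-simulated around the
#' fitted curves (Gaussian on the fraction scale for label data, Gaussian in
#' bp for the telomere difference, Gaussian in log10 units for vaccine
#' frequencies, with scales estimated from the fit residuals), the model is
#' refitted to each replicate (warm-started at the point estimate), and
#' percentile 2.5/97.5 intervals are taken.  Derived quantities inherit
#' their intervals from the bootstrap draws.  `method = "profile"` profiles
#' the objective over one named parameter instead.
#'
#' @param fit A [fit_model()] result.
#' @param B Number of bootstrap replicates.
#' @param method `"bootstrap"` or `"profile"`.
#' @param parameter For `method = "profile"`: name of the parameter to
#'   profile (on its natural scale).
#' @param n_grid Profile grid size.
#' @param level Confidence level (default 0.95).
#' @param refit_starts Number of cold Latin-hypercube starts per bootstrap
#'   refit in addition to the warm start at the point estimate (default 0:
#'   warm start only, which is standard for parametric-bootstrap refits).
#' @return A tibble with `term`, `estimate`, `conf.low`, `conf.high`; for
#'   the bootstrap, an attribute `failures` counts failed refits (a warning
#'   is issued above 20%).
#' @export
confidence_intervals <- function(fit, B = 200,
                                 method = c("bootstrap", "profile"),
                                 parameter = NULL, n_grid = 25, level = 0.95,
                                 refit_starts = 0) {
  method <- match.arg(method)
  if (method == "profile") {
    return(profile_interval(fit, parameter, n_grid, level))
  }
  data <- fit$data
  config <- fit$config
  tab <- fit$parameterization
  # fitted curves and residual scales
  pred_label <- if (!is.null(data$label) && "label" %in% config$datasets) {
    label_predictions(fit$kinetics, data$water, data$label)
  } else NULL
  sd_label <- if (!is.null(pred_label)) {
    stats::sd(pred_label - data$label$fraction_labelled)
  } else NULL
  pred_theta <- if (!is.null(data$telomere) && "telomere" %in% config$datasets) {
    theta_prediction(fit$kinetics, fit$telo)
  } else NULL
  sd_theta <- if (!is.null(pred_theta)) {
    if (!is.null(data$telomere$sd_bp)) data$telomere$sd_bp[1] else config$sigma$telomere
  } else NULL
  pred_yfv <- if (!is.null(data$yfv) && "yfv" %in% config$datasets) {
    log10(pmax(yfv_frequency(data$yfv$years_post_vaccination, fit$yfv), 1e-300))
  } else NULL
  sd_yfv <- if (!is.null(pred_yfv)) {
    stats::sd(pred_yfv - log10(pmax(data$yfv$frequency, 1e-12)))
  } else NULL

  warm <- as.list(fit$estimates)
  cfg_b <- config
  cfg_b$n_starts <- refit_starts
  draws <- vector("list", B)
  fails <- 0L
  for (b in seq_len(B)) {
    d_b <- data
    if (!is.null(pred_label)) {
      d_b$label$fraction_labelled <- pmax(pred_label + rnorm(length(pred_label), 0, sd_label), 0)
    }
    if (!is.null(pred_theta)) {
      d_b$telomere$theta_bp <- pred_theta + rnorm(1, 0, sd_theta)
    }
    if (!is.null(pred_yfv)) {
      d_b$yfv$frequency <- 10^(pred_yfv + rnorm(length(pred_yfv), 0, max(sd_yfv, 1e-3)))
    }
    f_b <- try(fit_model(d_b, cfg_b, extra_starts = list(warm)), silent = TRUE)
    if (inherits(f_b, "try-error")) { fails <- fails + 1L; next }
    draws[[b]] <- dplyr::bind_cols(
      tibble::as_tibble(as.list(f_b$estimates)), f_b$derived
    )
  }
  if (fails > 0.2 * B) {
    warn(sprintf("%d of %d bootstrap refits failed.", fails, B))
  }
  dr <- dplyr::bind_rows(draws)
  if (!nrow(dr)) abort("all bootstrap refits failed.")
  point <- dplyr::bind_cols(tibble::as_tibble(as.list(fit$estimates)), fit$derived)
  alpha <- (1 - level) / 2
  out <- purrr::map_dfr(names(dr), function(nm) {
    tibble::tibble(
      term = nm,
      estimate = point[[nm]][1],
      conf.low = quantile(dr[[nm]], alpha, na.rm = TRUE, names = FALSE),
      conf.high = quantile(dr[[nm]], 1 - alpha, na.rm = TRUE, names = FALSE)
    )
  })
  attr(out, "failures") <- fails
  attr(out, "draws") <- dr
  out
}

profile_interval <- function(fit, parameter, n_grid, level) {
  if (is.null(parameter)) abort("`parameter` must be given for profile CIs.")
  tab <- fit$parameterization
  if (!parameter %in% tab$name) abort("unknown parameter for profiling.")
  config <- fit$config
  data <- fit$data
  i <- match(parameter, tab$name)
  at_opt <- transform_vector(as.list(fit$estimates), tab)[i]
  grid <- sort(unique(c(seq(tab$lower[i], tab$upper[i],
                            length.out = n_grid), at_opt)))
  warm <- as.list(fit$estimates)
  if (parameter == "C") abort("profiling `C` is not supported; fix it via `C_mode`.")
  ssr_prof <- vapply(grid, function(g) {
    cfg <- config
    nat <- switch(tab$transform[i], log10 = 10^g, logit = plogis_(g), identity = g)
    cfg$bounds[[parameter]] <- c(nat * (1 - 1e-9), nat * (1 + 1e-9) + 1e-300)
    f <- try(fit_model(data, cfg, extra_starts = list(warm)), silent = TRUE)
    if (inherits(f, "try-error")) NA_real_ else f$ssr
  }, numeric(1))
  df2 <- fit$n_points - fit$n_par
  thresh <- fit$ssr * (1 + stats::qf(level, 1, df2) / df2)
  nat_grid <- vapply(grid, function(g) switch(tab$transform[i],
    log10 = 10^g, logit = plogis_(g), identity = g), numeric(1))
  inside <- which(!is.na(ssr_prof) & ssr_prof <= thresh)
  if (!length(inside)) abort("profile produced no points under the threshold.")
  tibble::tibble(
    term = parameter,
    estimate = fit$estimates[[parameter]],
    conf.low = min(nat_grid[inside]),
    conf.high = max(nat_grid[inside])
  )
}
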