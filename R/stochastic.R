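#' Deterministic clonal half-life
#'
#' The half-life of the *memory* carried by a clone — the time for an
#' antigen-specific clone of TSCM cells to halve — is `ln(2) / (d - p)`,
#' where `d` and `p` are the disappearance and proliferation rates.  This is
#' distinct from the population-replacement half-life: disappearance counts
#' death plus onward differentiation, so a clone can vanish while the pool
#' size is constant.
#'
#' @param d Disappearance rate, per day.
#' @param p Proliferation rate, per day.
#' @return Half-life in days.
#' @examples
#' deterministic_half_life(d = 0.004, p = 0.002)   # 346.6 days
#' @export
deterministic_half_life <- function(d, p) {
  if (any(d <= p)) abort("half-life requires `d > p` (a net-decaying clone).")
  log(2) / (d - p)
}

#' Clonal half-life / net-loss helpers
#'
#' `clonal_half_life()` is [deterministic_half_life()] without the domain
#' error (returns `Inf` for non-decaying clones); `net_loss_from_half_life()`
#' inverts it, converting a half-life in years to a net loss rate per day.
#'
#' @inheritParams deterministic_half_life
#' @return Days (`clonal_half_life`) or per-day rate
#'   (`net_loss_from_half_life`).
#' @export
clonal_half_life <- function(d, p) {
  ifelse(d > p, log(2) / (d - p), Inf)
}

#' @rdname clonal_half_life
#' @param half_life_years Half-life in years.
#' @export
net_loss_from_half_life <- function(half_life_years) {
  log(2) / (half_life_years * DAYS_PER_YEAR)
}

#' Initial size of a long-lived antigen-specific TSCM clone
#'
#' With a naive pool of about 1e11 cells, a naive precursor population
#' activated at per-day fraction `Delta` and bursting through `k` divisions
#' seeds `1e11 * 2^k * Delta` TSCM cells, of which a fraction `f` enters the
#' long-lived subpopulation.
#'
#' @param k Divisions in the clonal burst (0-20).
#' @param Delta Fraction of naive cells activated by the antigen, per day.
#' @param f Fraction of the burst entering the long-lived subpopulation
#'   (use `f = 1` for the bulk-pool convention).
#' @param naive_pool Size of the adult naive T-cell pool (default 1e11).
#' @return Rounded cell count.  Zero (with a warning) when `f = 0`: no
#'   long-lived clone is seeded.
#' @examples
#' initial_clone_size(k = 0, Delta = 1e-5, f = 1)      # 1e6
#' initial_clone_size(k = 10, Delta = 1e-5, f = 0.058) # ~5.94e7
#' @export
initial_clone_size <- function(k, Delta, f, naive_pool = 1e11) {
  stopifnot(k >= 0, Delta >= 0, f >= 0, f <= 1, naive_pool >= 0)
  n0 <- round(naive_pool * 2^k * Delta * f)
  if (n0 == 0) warn("initial clone size is 0: no long-lived clone seeded.")
  n0
}

#' Configuration for birth-death clone simulations
#'
#' @param p Proliferation rate, per day (>= 0).
#' @param d Disappearance rate, per day (>= 0).
#' @param n0 Initial clone size in cells (positive integer).
#' @param n_runs Number of independent realisations.
#' @param max_time Right-censoring horizon in days (default 100 years).
#' @param seed Optional integer seed applied before simulating.
#' @return An object of class `clone_sim_config`.
#' @export
clone_sim_config <- function(p, d, n0, n_runs = 1000,
                             max_time = 100 * DAYS_PER_YEAR, seed = NULL) {
  stopifnot(p >= 0, d >= 0, n0 >= 1, n_runs >= 1, max_time > 0)
  structure(list(p = p, d = d, n0 = round(n0), n_runs = n_runs,
                 max_time = max_time, seed = seed),
            class = "clone_sim_config")
}

#' Simulate clone fates with the exact Gillespie algorithm
#'
#' Runs `n_runs` exact stochastic realisations of a linear birth-death
#' process (division rate `x p`, disappearance rate `x d`, exponential
#' waiting times at total rate `x (p + d)`), reporting per-run extinction
#' times and population half-lives.  The half-life of a run is the first
#' passage of the trajectory at or below `n0 / 2`; runs still alive at
#' `max_time` are right-censored and flagged.
#'
#' @param config A [clone_sim_config()] object.
#' @return A tibble with one row per run: `run`, `extinction_time_days`,
#'   `half_life_days`, `censored`, `final_size`.  Summaries via
#'   [summarise_clone_fates()].
#' @examples
#' cfg <- clone_sim_config(p = 0, d = 0.01, n0 = 1, n_runs = 100, seed = 1)
#' fates <- simulate_clone(cfg)
#' mean(fates$extinction_time_days)   # ~ 1/d = 100 days
#' @export
simulate_clone <- function(config) {
  stopifnot(inherits(config, "clone_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$p + config$d == 0) {
    warn("p + d = 0: no events possible; returning censored runs.")
  }
  m <- gillespie_runs_cpp(config$n0, config$p, config$d,
                          config$max_time, config$n_runs)
  tibble::tibble(
    run = seq_len(nrow(m)),
    extinction_time_days = m[, "extinction_time"],
    half_life_days = m[, "half_life"],
    censored = m[, "censored"] > 0,
    final_size = m[, "final_size"]
  )
}

#' Simulate a single clone trajectory
#'
#' As [simulate_clone()] but for one realisation, returning the trajectory
#' itself (thinned to every `record_every`-th event for large clones).
#'
#' @inheritParams simulate_clone
#' @param record_every Record every m-th event (the initial state and the
#'   final event are always kept).
#' @return A tibble with columns `time_days`, `size`, carrying attributes
#'   `extinction_time`, `half_life`, `censored`.
#' @export
simulate_clone_trajectory <- function(config, record_every = 1L) {
  stopifnot(inherits(config, "clone_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  r <- gillespie_clone_cpp(config$n0, config$p, config$d, config$max_time,
                           record = TRUE, record_every = record_every)
  out <- tibble::tibble(time_days = r$trajectory_t, size = r$trajectory_x)
  attr(out, "extinction_time") <- r$extinction_time
  attr(out, "half_life") <- r$half_life
  attr(out, "censored") <- r$censored
  out
}

#' Summarise simulated clone fates
#'
#' @param fates A tibble from [simulate_clone()].
#' @return A one-row tibble with medians, means and quartiles of the
#'   extinction times and half-lives, and the censoring fraction.
#' @export
summarise_clone_fates <- function(fates) {
  q <- function(x, p) quantile(x, p, na.rm = TRUE, names = FALSE)
  tibble::tibble(
    n_runs = nrow(fates),
    frac_censored = mean(fates$censored),
    mean_extinction_days = mean(fates$extinction_time_days, na.rm = TRUE),
    median_extinction_days = q(fates$extinction_time_days, 0.5),
    q25_extinction_days = q(fates$extinction_time_days, 0.25),
    q75_extinction_days = q(fates$extinction_time_days, 0.75),
    median_half_life_days = q(fates$half_life_days, 0.5),
    q25_half_life_days = q(fates$half_life_days, 0.25),
    q75_half_life_days = q(fates$half_life_days, 0.75)
  )
}

#' Distribution of antigen-specific precursor lifespans
#'
#' The precursor lifespan is the time until the last cell of an
#' antigen-specific clone disappears.  In `mode = "bulk"` the bulk-pool
#' convention is used (`Delta` fixed at the representative value 1e-5 and
#' `f = 1`, rates from the one-pool model); in `mode = "long_lived"` the
#' fitted `Delta` and `f` of the explicit model seed a clone in the slow
#' subpopulation with its rates.
#'
#' @param params An [implicit_params()] (bulk mode) or [explicit_params()]
#'   (long-lived mode) object.  For bulk mode `Delta` defaults to 1e-5 if
#'   the parameter object does not carry one.
#' @param mode `"bulk"` or `"long_lived"`.
#' @param n_runs Number of realisations.
#' @param seed Optional integer seed.
#' @param max_time Censoring horizon, days.
#' @return A list with `fates` (per-run tibble), `summary`
#'   (one-row tibble) and `n0` (the seeded clone size).
#' @export
precursor_lifespan_distribution <- function(params,
                                            mode = c("bulk", "long_lived"),
                                            n_runs = 1000, seed = NULL,
                                            max_time = 100 * DAYS_PER_YEAR) {
  mode <- match.arg(mode)
  if (mode == "bulk") {
    stopifnot(inherits(params, "implicit_params"))
    Delta <- if (!is.null(params$Delta)) params$Delta else 1e-5
    n0 <- initial_clone_size(params$k, Delta, f = 1)
    p <- params$p_s
    d <- params$d_s
  } else {
    stopifnot(inherits(params, "explicit_params"))
    if (is.null(params$Delta)) {
      abort("long-lived mode needs `Delta` on the explicit parameter object.")
    }
    n0 <- initial_clone_size(params$k, params$Delta, params$f)
    p <- params$p_s2
    d <- params$d_s2
  }
  if (n0 == 0) {
    fates <- tibble::tibble(run = integer(), extinction_time_days = numeric(),
                            half_life_days = numeric(), censored = logical(),
                            final_size = numeric())
    return(list(fates = fates, summary = summarise_clone_fates(fates), n0 = 0))
  }
  cfg <- clone_sim_config(p = p, d = d, n0 = n0, n_runs = n_runs,
                          max_time = max_time, seed = seed)
  fates <- simulate_clone(cfg)
  list(fates = fates, summary = summarise_clone_fates(fates), n0 = n0)
}

#' Degree of self-renewal
#'
#' The mean time a cell (and its progeny) resides in a compartment at steady
#' state without dying or differentiating: `1 / (d - p)`.  Equivalently, at
#' steady state it equals the compartment size divided by its upstream
#' input flux, `T_SCM2 / (Delta 2^k f T_N)`; both forms are computed and
#' cross-checked when the parameter object carries the flux information.
#' A non-decaying compartment (`d <= p`, perfect self-renewal) returns
#' `Inf`.
#'
#' @param params An [explicit_params()] or [implicit_params()] object, or a
#'   bare list with elements `d` and `p`.
#' @param subpopulation For explicit parameters, `"slow"` (default) or
#'   `"fast"`.
#' @return Days.
#' @examples
#' # Table-style slow half-life of 8.74 years:
#' d2 <- net_loss_from_half_life(8.74)
#' degree_of_self_renewal(list(d = 0.002 + d2, p = 0.002))   # ~4600 days
#' @export
degree_of_self_renewal <- function(params, subpopulation = c("slow", "fast")) {
  subpopulation <- match.arg(subpopulation)
  if (inherits(params, "explicit_params")) {
    if (subpopulation == "slow") {
      d <- params$d_s2; p <- params$p_s2; a <- params$a2
    } else {
      d <- params$d_s1; p <- params$p_s1; a <- params$a1
    }
    # cross-check: size / influx = 1 / (a * 2^k) must equal 1 / (d - p)
    alt <- 1 / (a * 2^params$k)
    if (is.finite(alt) && abs(alt - 1 / (d - p)) > 1e-8 * alt) {
      abort("internal inconsistency between rate and flux forms of self-renewal.")
    }
  } else if (inherits(params, "implicit_params")) {
    d <- params$d_s; p <- params$p_s
  } else {
    d <- params$d; p <- params$p
  }
  if (d <= p) return(Inf)
  1 / (d - p)
}
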