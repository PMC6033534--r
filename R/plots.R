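#' Plot a fitted label model against the data
#'
#' Shows the measured label fractions and the fitted naive and TSCM curves;
#' when a vaccine cohort is part of the fit, a second panel shows the
#' biexponential decay on a log10 frequency axis.
#'
#' @param object A `tscm_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tscm_fit <- function(object, ...) {
  d <- object$data$label
  tt <- seq(0, max(d$time_days), length.out = 200)
  kin <- object$kinetics
  pred <- if (inherits(kin, "implicit_params")) {
    solve_label_implicit(kin, object$data$water, tt)
  } else {
    solve_label_explicit(kin, object$data$water, tt)
  }
  curves <- tidyr::pivot_longer(
    dplyr::select(pred, "time_days", "F_TN", "F_TSCM"),
    cols = c("F_TN", "F_TSCM"), names_to = "population",
    values_to = "fraction_labelled"
  ) |>
    dplyr::mutate(population = dplyr::recode(.data$population,
                                             F_TN = "naive", F_TSCM = "tscm"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_days,
                                  y = .data$fraction_labelled,
                                  colour = .data$population)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves) +
    ggplot2::labs(x = "time (days)", y = "fraction labelled DNA",
                  colour = NULL,
                  title = sprintf("%s model fit (k = %d)",
                                  object$config$variant,
                                  as.integer(object$config$k))) +
    ggplot2::theme_minimal()
}

#' Plot a clonal-expansion scan
#'
#' One panel per summary column: objective, self-renewal fraction, clonal
#' half-life, and expected precursor lifespan, each against `k`.
#'
#' @param object A `tscm_kscan` tibble from [k_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tscm_kscan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, -"fit"),
    cols = -"k", names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "clonal expansion k", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot simulated clone-fate distributions
#'
#' @param fates A tibble from [simulate_clone()].
#' @param what `"half_life"` or `"extinction"`.
#' @return A ggplot object.
#' @export
plot_clone_fates <- function(fates, what = c("half_life", "extinction")) {
  what <- match.arg(what)
  col <- if (what == "half_life") "half_life_days" else "extinction_time_days"
  ggplot2::ggplot(fates, ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::labs(x = paste(gsub("_", " ", col)), y = "runs") +
    ggplot2::theme_minimal()
}

#' Plot body-water fits against saliva measurements
#'
#' @param saliva Saliva tibble (`subject_id`, `time_days`, `enrichment`).
#' @param fits Result of [fit_water()].
#' @return A ggplot object.
#' @export
plot_water_fit <- function(saliva, fits) {
  tt <- seq(0, max(saliva$time_days), length.out = 200)
  curves <- purrr::pmap_dfr(fits, function(subject_id, f_r, delta_w, beta_s,
                                           tau, ...) {
    tibble::tibble(
      subject_id = subject_id, time_days = tt,
      enrichment = water_enrichment(tt, body_water_params(f_r, delta_w,
                                                          beta_s, tau))
    )
  })
  ggplot2::ggplot(saliva, ggplot2::aes(x = .data$time_days,
                                       y = .data$enrichment)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves, colour = "steelblue") +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::labs(x = "time (days)", y = "saliva enrichment") +
    ggplot2::theme_minimal()
}
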