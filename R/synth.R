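#' Study design for synthetic data generation
#'
#' Describes the sampling structure of a heavy-water labelling study with
#' telomere and vaccine-cohort add-ons: a 7-week (49-day) labelling period,
#' around ten DNA-enrichment sampling times over roughly 300 days in five
#' subjects and two lineages, a denser saliva series for the body-water
#' curve, one telomere-length difference per subject and lineage, and a
#' cross-sectional vaccine cohort of 37 subjects spanning 0.27-35 years
#' post-vaccination.
#'
#' @param n_subjects Number of labelled subjects.
#' @param tau Label-cessation time, days.
#' @param label_times DNA-enrichment sampling times, days.
#' @param saliva_times Saliva sampling times, days.
#' @param lineages Lineages measured.
#' @param sigma_label Gaussian measurement sd for label fractions
#'   (fraction units).
#' @param sigma_saliva Gaussian measurement sd for saliva enrichment.
#' @param sigma_theta Gaussian measurement sd for the telomere difference,
#'   bp.
#' @param sigma_yfv_log10 Lognormal (log10-scale) measurement sd for vaccine
#'   frequencies.
#' @param yfv_n Vaccine cohort size.
#' @param yfv_range Time range of the cross-section, years; sampling times
#'   are drawn log-uniformly over it to mimic the observed spread.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 5, tau = 49,
                         label_times = c(7, 14, 21, 35, 49, 63, 91, 133, 203, 301),
                         saliva_times = c(1, 3, 7, 14, 21, 28, 35, 42, 49, 56, 70, 91),
                         lineages = c("CD4", "CD8"),
                         sigma_label = 5e-4, sigma_saliva = 2e-3,
                         sigma_theta = 150, sigma_yfv_log10 = 0.3,
                         yfv_n = 37, yfv_range = c(0.27, 35)) {
  stopifnot(n_subjects >= 1, tau > 0, !is.unsorted(label_times),
            all(label_times >= 0), sigma_label >= 0, sigma_theta >= 0,
            sigma_yfv_log10 >= 0, yfv_n >= 1, yfv_range[1] > 0,
            yfv_range[2] > yfv_range[1])
  structure(
    list(n_subjects = n_subjects, tau = tau, label_times = label_times,
         saliva_times = saliva_times, lineages = lineages,
         sigma_label = sigma_label, sigma_saliva = sigma_saliva,
         sigma_theta = sigma_theta, sigma_yfv_log10 = sigma_yfv_log10,
         yfv_n = yfv_n, yfv_range = yfv_range),
    class = "study_design"
  )
}

#' Reference ground-truth parameter set
#'
#' A plausible ground truth for simulation studies: subpopulation clonal
#' half-lives of 0.41 and 8.74 years, burst fraction `f = 0.058` entering
#' the slow subpopulation, naive proliferation 5e-4 per day, fast and slow
#' TSCM proliferation 0.015 and 0.002 per day, telomere loss 50
#' bp/division with one uncompensated burst division, and a vaccine-cohort
#' amplitude of 1e-4.
#'
#' @param k Clonal-burst divisions.
#' @param Delta Absolute naive recruitment fraction per day (used only for
#'   clone seeding).
#' @return A list with elements `water`, `kinetics`, `telomere`, `A`.
#' @export
default_truth <- function(k = 2, Delta = 1e-5) {
  kin <- explicit_params(
    p_n = 5e-4, f = 0.058,
    p_s1 = 0.015, d_s1 = 0.015 + net_loss_from_half_life(0.41),
    p_s2 = 0.002, d_s2 = 0.002 + net_loss_from_half_life(8.74),
    k = k, c = 1, Delta = Delta
  )
  list(
    water = body_water_params(f_r = 0.045, delta_w = 0.07, beta_s = 0.002,
                              tau = 49),
    kinetics = kin,
    telomere = telomere_params(delta_bp = 50, C = min(1, k)),
    A = 1e-4
  )
}

#' Generate a complete synthetic study
#'
#' Evaluates the noise-free model curves at the design's sampling times and
#' adds seeded measurement noise: additive Gaussian on the fraction scale
#' for saliva and label data (label fractions truncated at zero), additive
#' Gaussian in bp for the telomere difference, and multiplicative
#' log-normal for vaccine frequencies.  The ground truth is stored on the
#' returned object, separate from the observables, for recovery scoring.
#'
#' @param truth A list as from [default_truth()]: `water`
#'   ([body_water_params()]), `kinetics` ([explicit_params()]),
#'   `telomere` ([telomere_params()]), `A` (vaccine amplitude).
#' @param design A [study_design()] object.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return An object of class `tscm_study`: tibbles `saliva`, `label`,
#'   `telomere`, `yfv`, plus `truth` and `design`.
#' @examples
#' study <- generate_study(default_truth(), study_design(), seed = 42)
#' head(study$label)
#' @export
generate_study <- function(truth = default_truth(), design = study_design(),
                           seed = 1) {
  stopifnot(inherits(design, "study_design"),
            inherits(truth$water, "body_water_params"),
            inherits(truth$kinetics, "explicit_params"),
            inherits(truth$telomere, "telomere_params"))
  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(design$n_subjects))
  water <- truth$water

  saliva <- tidyr::expand_grid(subject_id = subjects,
                               time_days = design$saliva_times) |>
    dplyr::mutate(
      enrichment = pmin(pmax(
        water_enrichment(.data$time_days, water) +
          rnorm(dplyr::n(), 0, design$sigma_saliva), 0), 1)
    )

  curves <- solve_label_explicit(truth$kinetics, water, design$label_times)
  label <- tidyr::expand_grid(subject_id = subjects,
                              lineage = design$lineages,
                              population = c("naive", "tscm"),
                              time_days = design$label_times) |>
    dplyr::mutate(
      mu = dplyr::if_else(
        .data$population == "naive",
        curves$F_TN[match(.data$time_days, design$label_times)],
        curves$F_TSCM[match(.data$time_days, design$label_times)]
      ),
      fraction_labelled = pmax(.data$mu + rnorm(dplyr::n(), 0, design$sigma_label), 0)
    ) |>
    dplyr::select(-"mu")

  theta_true <- theta_explicit(truth$kinetics, truth$telomere)$theta_bp
  telomere <- tidyr::expand_grid(subject_id = subjects,
                                 lineage = design$lineages) |>
    dplyr::mutate(
      theta_bp = theta_true + rnorm(dplyr::n(), 0, design$sigma_theta),
      sd_bp = design$sigma_theta
    )

  yfv_pars <- link_explicit_to_yfv(truth$kinetics, A = truth$A)
  lr <- log(design$yfv_range)
  yfv_times <- exp(runif(design$yfv_n, lr[1], lr[2]))
  yfv <- tibble::tibble(
    subject_id = sprintf("V%02d", seq_len(design$yfv_n)),
    years_post_vaccination = yfv_times,
    frequency = yfv_frequency(yfv_times, yfv_pars) *
      10^rnorm(design$yfv_n, 0, design$sigma_yfv_log10)
  )

  structure(
    list(saliva = saliva, label = label, telomere = telomere, yfv = yfv,
         truth = truth, design = design, seed = seed),
    class = "tscm_study"
  )
}

#' @export
print.tscm_study <- function(x, ...) {
  cat("Synthetic labelling study\n")
  cat(sprintf("  %d subjects x %s; %d label points, %d saliva points\n",
              x$design$n_subjects, paste(x$design$lineages, collapse = "/"),
              nrow(x$label), nrow(x$saliva)))
  cat(sprintf("  %d telomere observations; vaccine cohort n = %d\n",
              nrow(x$telomere), if (is.null(x$yfv)) 0L else nrow(x$yfv)))
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' Extract one subject's data as a fitting bundle
#'
#' @param study A `tscm_study` (or a list of the same shape from
#'   [read_study()]).
#' @param subject Subject id (default: first).
#' @param lineage Lineage to keep (default `"CD8"`).
#' @param water `"fit"` (default) refits the body-water curve to the
#'   subject's saliva series; `"truth"` uses the generator's parameters.
#' @param include_yfv Attach the vaccine cohort (shared across subjects).
#' @return A [fit_data()] bundle.
#' @export
study_subset <- function(study, subject = NULL, lineage = "CD8",
                         water = c("fit", "truth"), include_yfv = FALSE) {
  water <- match.arg(water)
  if (is.null(subject)) subject <- study$label$subject_id[1]
  sal <- dplyr::filter(study$saliva, .data$subject_id == subject)
  bw <- if (water == "truth") {
    if (is.null(study$truth)) abort("study carries no ground truth water parameters.")
    study$truth$water
  } else {
    as_body_water_params(fit_water(dplyr::select(sal, -"subject_id"),
                                   tau = study$design$tau %||% 49))
  }
  lab <- dplyr::filter(study$label, .data$subject_id == subject,
                       .data$lineage == .env$lineage) |>
    dplyr::select("population", "time_days", "fraction_labelled")
  tel <- dplyr::filter(study$telomere, .data$subject_id == subject,
                       .data$lineage == .env$lineage) |>
    dplyr::select("theta_bp", dplyr::any_of("sd_bp"))
  fit_data(water = bw, label = lab,
           telomere = if (nrow(tel)) tel[1, ] else NULL,
           yfv = if (include_yfv) study$yfv else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replicated generate-fit-score recovery experiment
#'
#' Repeats the closed loop "generate a synthetic study, fit the configured
#' model to one subject's data, score the estimates against the ground
#' truth" and summarises bias, root-mean-square error, and the fraction of
#' replicates whose slow half-life lands within a target range.
#'
#' @param truth Ground truth, as for [generate_study()].
#' @param design A [study_design()] object.
#' @param config A [fit_config()] object.
#' @param n_replicates Number of replicates.
#' @param seed Master seed; per-replicate seeds are drawn from it.
#' @param lineage Lineage fitted.
#' @param water `"fit"` (default) refits the body-water curve per replicate
#'   (full closed loop); `"truth"` uses the generating parameters.
#' @param hl_range Target range (years) used for the slow half-life
#'   coverage column of the summary.
#' @return A list with `replicates` (one row per replicate: estimates and
#'   derived quantities plus their truth) and `summary` (bias/RMSE per
#'   quantity).
#' @export
recovery_experiment <- function(truth = default_truth(),
                                design = study_design(),
                                config = fit_config(variant = "explicit",
                                                    datasets = c("label", "telomere", "yfv"),
                                                    k = 2),
                                n_replicates = 25, seed = 1,
                                lineage = "CD8", water = c("fit", "truth"),
                                hl_range = c(5, 15)) {
  water <- match.arg(water)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_replicates)
  truth_row <- truth_quantities(truth, config)
  rows <- purrr::map(seq_len(n_replicates), function(i) {
    study <- generate_study(truth, design, seed = rep_seeds[i])
    include_yfv <- "yfv" %in% config$datasets
    fd <- study_subset(study, lineage = lineage, water = water,
                       include_yfv = include_yfv)
    cfg <- config
    cfg$seed <- rep_seeds[i]
    fit <- fit_model(fd, cfg)
    dplyr::bind_cols(
      tibble::tibble(replicate = i, seed = rep_seeds[i], ssr = fit$ssr),
      tibble::as_tibble(as.list(fit$estimates)), fit$derived
    )
  })
  replicates <- dplyr::bind_rows(rows)
  common <- intersect(names(truth_row), names(replicates))
  summary <- purrr::map_dfr(common, function(nm) {
    est <- replicates[[nm]]; tv <- truth_row[[nm]]
    tibble::tibble(
      quantity = nm, truth = tv,
      median_estimate = median(est, na.rm = TRUE),
      bias = mean(est, na.rm = TRUE) - tv,
      rmse = sqrt(mean((est - tv)^2, na.rm = TRUE))
    )
  })
  hl_in_range <- if ("half_life_slow_years" %in% names(replicates)) {
    mean(replicates$half_life_slow_years >= hl_range[1] &
           replicates$half_life_slow_years <= hl_range[2])
  } else NA_real_
  list(replicates = replicates, summary = summary,
       truth = truth_row, frac_slow_hl_in_range = hl_in_range)
}

truth_quantities <- function(truth, config) {
  kin <- truth$kinetics
  if (config$variant == "explicit") {
    tibble::tibble(
      p_n = kin$p_n, f = kin$f, p_s1 = kin$p_s1, p_s2 = kin$p_s2,
      net_loss1 = kin$d_s1 - kin$p_s1, net_loss2 = kin$d_s2 - kin$p_s2,
      c = kin$c, A = truth$A,
      half_life_fast_years = clonal_half_life(kin$d_s1, kin$p_s1) / DAYS_PER_YEAR,
      half_life_slow_years = clonal_half_life(kin$d_s2, kin$p_s2) / DAYS_PER_YEAR,
      rel_size_slow = kin$rel_size_slow,
      self_renewal_slow_days = degree_of_self_renewal(kin, "slow")
    )
  } else {
    agg <- collapse_explicit(kin)
    tibble::tibble(
      p_n = agg$p_n, p_s = agg$p_s, delta_ratio = agg$delta_ratio,
      ds_star = agg$ds_star, c = agg$c
    )
  }
}
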