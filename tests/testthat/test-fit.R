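test_that("nested F-test matches the F distribution and guards preconditions", {
  # identical fits: no evidence
  t0 <- f_test_nested(1.5, 1.5, n_points = 20, p_reduced = 3, p_full = 4)
  expect_equal(t0$F, 0)
  expect_equal(t0$p_value, 1)
  # halving the SSR with one extra parameter out of 20 points
  t1 <- f_test_nested(2, 1, n_points = 20, p_reduced = 4, p_full = 5)
  expect_equal(t1$F, 15)
  # independent oracle: F upper tail via the incomplete-beta identity
  p_beta <- stats::pbeta(15 / (15 + 15 * 1), 1 / 2, 15 / 2,
                         lower.tail = FALSE)
  expect_equal(t1$p_value, p_beta, tolerance = 1e-12)
  expect_equal(t1$p_value, 0.0015018, tolerance = 1e-4)
  expect_error(f_test_nested(1, 2, 20, 4, 5), "ssr_reduced")
  expect_error(f_test_nested(2, 1, 20, 5, 5), "p_full")
  expect_error(f_test_nested(2, 1, 5, 4, 5), "n_points")
})

test_that("Fisher pooling of p-values matches the chi-square combination", {
  expect_equal(pool_pvalues(c(1, 1, 1))$pooled_p, 1)
  expect_equal(pool_pvalues(0.2)$pooled_p, 0.2, tolerance = 1e-12)
  p2 <- pool_pvalues(c(0.5, 0.5))
  expect_equal(p2$statistic, -2 * 2 * log(0.5), tolerance = 1e-12)
  # oracle: chi-square upper tail with 4 df
  expect_equal(p2$pooled_p,
               stats::pchisq(2.772589, df = 4, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(p2$pooled_p, 0.5966, tolerance = 1e-4)
  expect_error(pool_pvalues(numeric(0)), "empty")
  expect_error(pool_pvalues(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("combined SSR vanishes at truth and respects the weighting strategies", {
  tr <- default_truth()
  des0 <- study_design(sigma_label = 0, sigma_saliva = 0, sigma_theta = 0,
                       sigma_yfv_log10 = 0)
  st <- generate_study(tr, des0, seed = 3)
  fd <- study_subset(st, lineage = "CD8", water = "truth", include_yfv = TRUE)
  cfg <- fit_config(variant = "explicit",
                    datasets = c("label", "telomere", "yfv"), k = 2)
  yfv <- link_explicit_to_yfv(tr$kinetics, A = tr$A)
  s <- combined_ssr(fd, tr$kinetics, tr$telomere, yfv, cfg)
  expect_lt(s$total, 1e-10)

  # single dataset with unit weights reduces to the plain SSR
  cfg1 <- fit_config(variant = "explicit", datasets = "label",
                     weighting = "equal", k = 2)
  st2 <- generate_study(tr, study_design(), seed = 4)
  fd2 <- study_subset(st2, lineage = "CD8", water = "truth")
  pred <- tscmdyn:::label_predictions(tr$kinetics, fd2$water, fd2$label)
  plain <- sum((pred - fd2$label$fraction_labelled)^2)
  s2 <- combined_ssr(fd2, tr$kinetics, tr$telomere, NULL, cfg1)
  expect_equal(s2$total, plain, tolerance = 1e-12)

  # variance strategy: sum of per-dataset SSR / (n_i sigma_i^2), by hand
  cfgv <- fit_config(variant = "explicit", datasets = c("label", "telomere"),
                     weighting = "variance", k = 2,
                     sigma = list(label = 2e-3, telomere = 100))
  fd3 <- fd2
  fd3$telomere$sd_bp <- NULL
  sv <- combined_ssr(fd3, tr$kinetics, tr$telomere, NULL, cfgv)
  theta_resid <- tscmdyn:::theta_prediction(tr$kinetics, tr$telomere) -
    fd3$telomere$theta_bp[1]
  by_hand <- plain / (nrow(fd3$label) * (2e-3)^2) + theta_resid^2 / (1 * 100^2)
  expect_equal(sv$total, by_hand, tolerance = 1e-12)

  # sigma strategy drops the count normalisation
  cfgs <- fit_config(variant = "explicit", datasets = c("label", "telomere"),
                     weighting = "sigma", k = 2,
                     sigma = list(label = 2e-3, telomere = 100))
  ss <- combined_ssr(fd3, tr$kinetics, tr$telomere, NULL, cfgs)
  expect_equal(ss$total, plain / (2e-3)^2 + theta_resid^2 / 100^2,
               tolerance = 1e-12)
})

test_that("fits are deterministic, at a fixed point, and k_scan degenerates to fit_model", {
  st <- generate_study(default_truth(), study_design(), seed = 9)
  fd <- study_subset(st, lineage = "CD8", water = "truth")
  cfg <- fit_config(k = 2, n_starts = 6, seed = 21)
  f1 <- fit_model(fd, cfg)
  f2 <- fit_model(fd, cfg)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$ssr, f2$ssr)
  # refitting from the returned optimum leaves the objective unchanged
  f3 <- fit_model(fd, cfg, extra_starts = list(as.list(f1$estimates)))
  expect_lt(abs(f3$ssr - f1$ssr) / f1$ssr, 1e-8)
  ks <- k_scan(fd, cfg, k_values = 2)
  expect_equal(ks$ssr, f1$ssr, tolerance = 1e-10)
  expect_equal(ks$half_life_years,
               log(2) / (f1$kinetics$d_s - f1$kinetics$p_s) / 365.25)
})

test_that("SSR profile is nearly flat in the clonal-expansion size", {
  st <- generate_study(default_truth(), study_design(), seed = 42)
  fd <- study_subset(st, lineage = "CD8", water = "truth")
  ks <- k_scan(fd, fit_config(n_starts = 8, seed = 3),
               k_values = c(0, 2, 5, 10, 15))
  expect_lt(max(ks$ssr) / min(ks$ssr), 1.25)
})

test_that("homogeneity is rejected on heterogeneous data and the nesting inequality holds", {
  st <- generate_study(default_truth(), study_design(), seed = 1001)
  fd <- study_subset(st, lineage = "CD8", water = "truth")
  th <- test_homogeneity(fd, fit_config(k = 2, n_starts = 8, seed = 5))
  expect_gte(th$fit_reduced$ssr, th$fit_full$ssr)
  expect_lt(th$test$p_value, 0.05)
  # naive-pool heterogeneity flag adds exactly one parameter
  cfg_nh <- fit_config(k = 2, n_starts = 4, seed = 5,
                       naive_heterogeneity = TRUE)
  f_nh <- fit_model(fd, cfg_nh)
  expect_true("dn_loss" %in% names(f_nh$estimates))
  expect_equal(f_nh$n_par, th$fit_full$n_par + 1L)
})

test_that("implicit-model fits recover the labelled-DNA disappearance rate", {
  # truth: clonal half-life 0.5 years, heterogeneous labelled-DNA loss
  k <- 2
  dr <- log(2) / (0.5 * 365.25) / 2^k
  truth <- implicit_params(p_n = 5e-4, p_s = 0.01, delta_ratio = dr, k = k,
                           ds_star = 0.02)
  telo <- telomere_params(delta_bp = 50, C = 1)
  bw <- body_water_params(0.045, 0.07, 0.002)
  tt <- c(7, 14, 21, 35, 49, 63, 91, 133, 203, 301)
  curves <- solve_label_implicit(truth, bw, tt)
  theta_true <- theta_steady_state(truth, telo)
  sd_lab <- 0.1 * mean(c(curves$F_TN, curves$F_TSCM))  # 10% of typical signal
  set.seed(77)
  hits <- replicate(50, {
    lab <- tibble::tibble(
      population = rep(c("naive", "tscm"), each = length(tt)),
      time_days = rep(tt, 2),
      fraction_labelled = pmax(c(curves$F_TN, curves$F_TSCM) +
                                 rnorm(2 * length(tt), 0, sd_lab), 0)
    )
    fd <- fit_data(bw, label = lab,
                   telomere = tibble::tibble(theta_bp = theta_true +
                                               rnorm(1, 0, 150), sd_bp = 150))
    cfg <- fit_config(variant = "implicit", k = k, n_starts = 5,
                      seed = sample.int(1e6, 1),
                      sigma = list(label = sd_lab, telomere = 150))
    fit <- fit_model(fd, cfg)
    abs(fit$estimates[["ds_star"]] / truth$ds_star - 1) < 0.25
  })
  expect_gte(mean(hits), 0.9)
})

test_that("constrained fits report compatibility correctly", {
  st <- generate_study(default_truth(), study_design(), seed = 42)
  fd <- study_subset(st, lineage = "CD8", water = "truth", include_yfv = TRUE)
  cfg <- fit_config(variant = "explicit",
                    datasets = c("label", "telomere", "yfv"), k = 2,
                    n_starts = 12, seed = 3)
  cf <- constrained_fit(fd, cfg)
  # truth half-life 8.74 y lies inside [5, 15]: constraint costs nothing
  expect_true(cf$compatible)
  expect_lt(abs(cf$fit_constrained$ssr - cf$fit_unconstrained$ssr),
            1e-6 * cf$fit_unconstrained$ssr + 1e-8)
  hl <- cf$fit_constrained$derived$half_life_slow_years
  expect_gte(hl, 5); expect_lte(hl, 15)

  # uniformly fast truth with tight noise: the constraint must hurt
  fast <- default_truth()
  fast$kinetics <- explicit_params(
    p_n = 5e-4, f = 0.5, p_s1 = 0.015,
    d_s1 = 0.015 + net_loss_from_half_life(0.2),
    p_s2 = 0.014, d_s2 = 0.014 + net_loss_from_half_life(0.25),
    k = 2, Delta = 1e-5
  )
  st2 <- generate_study(fast, study_design(sigma_label = 2e-4,
                                           sigma_theta = 50,
                                           sigma_yfv_log10 = 0.1), seed = 8)
  fd2 <- study_subset(st2, lineage = "CD8", water = "truth",
                      include_yfv = TRUE)
  cf2 <- constrained_fit(fd2, cfg)
  expect_false(cf2$compatible)
  expect_gt(cf2$fit_constrained$ssr, cf2$fit_unconstrained$ssr)
})

test_that("explicit fits canonicalise subpopulation order and bound structure", {
  st <- generate_study(default_truth(), study_design(), seed = 13)
  fd <- study_subset(st, lineage = "CD8", water = "truth", include_yfv = TRUE)
  cfg <- fit_config(variant = "explicit",
                    datasets = c("label", "telomere", "yfv"), k = 2,
                    n_starts = 10, seed = 2)
  fit <- fit_model(fd, cfg)
  expect_lte(fit$derived$half_life_fast_years,
             fit$derived$half_life_slow_years)
  expect_gt(fit$derived$rel_size_slow, 0)
  expect_lt(fit$derived$rel_size_slow, 1)
})

test_that("configuration and data validation fail fast", {
  expect_error(fit_config(datasets = "yfv", variant = "implicit"),
               "explicit")
  expect_error(fit_config(datasets = character(0)), "at least one")
  st <- generate_study(default_truth(), study_design(), seed = 2)
  fd <- study_subset(st, lineage = "CD8")      # no vaccine data attached
  cfg <- fit_config(variant = "explicit",
                    datasets = c("label", "telomere", "yfv"), k = 2)
  expect_error(fit_model(fd, cfg), "vaccine")
  # more parameters than points
  tiny <- fit_data(
    bw_default(),
    label = tibble::tibble(population = c("naive", "tscm", "tscm"),
                           time_days = c(10, 10, 20),
                           fraction_labelled = c(0.001, 0.002, 0.002))
  )
  expect_error(fit_model(tiny, fit_config(datasets = "label", k = 2)),
               "insufficient data")
  expect_error(fit_model(fd, fit_config(k = 2, n_starts = 0)),
               "extra_starts")
})

test_that("bootstrap intervals contain the point estimate and collapse without noise", {
  tr <- default_truth()
  st <- generate_study(tr, study_design(), seed = 31)
  fd <- study_subset(st, lineage = "CD8", water = "truth")
  cfg <- fit_config(k = 2, n_starts = 5, seed = 3)
  fit <- fit_model(fd, cfg)
  set.seed(99)
  ci <- confidence_intervals(fit, B = 40)
  for (i in seq_len(nrow(ci))) {
    expect_gte(ci$estimate[i], ci$conf.low[i] - 1e-8)
    expect_lte(ci$estimate[i], ci$conf.high[i] + 1e-8)
  }
  # derived half-life interval is the transform of the bootstrap draws
  draws <- attr(ci, "draws")
  hl <- log(2) / (2^2 * draws$delta_ratio) / 365.25
  expect_equal(ci$conf.low[ci$term == "half_life_years"],
               unname(quantile(hl, 0.025)), tolerance = 1e-6)
  # noise-free data: intervals collapse onto the estimate (telomerase
  # compensation pinned: with a single exact telomere point, C and the
  # naive influx trade off along a flat direction)
  tr0 <- tr
  tr0$kinetics <- explicit_params(p_n = 5e-4, f = 0.5, p_s1 = 0.01,
                                  d_s1 = 0.0133, p_s2 = 0.01, d_s2 = 0.0133,
                                  k = 2)   # homogeneous: one-pool model exact
  tr0$telomere <- telomere_params(delta_bp = 50, C = 0)
  st0 <- generate_study(tr0, study_design(sigma_label = 0, sigma_saliva = 0,
                                          sigma_theta = 0), seed = 5)
  fd0 <- study_subset(st0, lineage = "CD8", water = "truth")
  fit0 <- fit_model(fd0, fit_config(k = 2, n_starts = 5, seed = 3,
                                    C_mode = "zero"))
  ci0 <- confidence_intervals(fit0, B = 10)
  expect_lt(max(ci0$conf.high - ci0$conf.low), 1e-4)
})

test_that("profile intervals bracket the optimum for an identified parameter", {
  st <- generate_study(default_truth(), study_design(), seed = 17)
  fd <- study_subset(st, lineage = "CD8", water = "truth")
  cfg <- fit_config(k = 2, n_starts = 5, seed = 3)
  fit <- fit_model(fd, cfg)
  pr <- confidence_intervals(fit, method = "profile", parameter = "p_n",
                             n_grid = 15)
  expect_lte(pr$conf.low, fit$estimates[["p_n"]])
  expect_gte(pr$conf.high, fit$estimates[["p_n"]])
})
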