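# Replicated simulation experiments used to calibrate and stress the
# statistical machinery.  These are ordinary exported functions so the same
# loops back the test suite and the reproduction script.

#' Null calibration of the homogeneity F-test
#'
#' Generates replicate studies from a kinetically homogeneous ground truth
#' (two identical TSCM subpopulations, which collapse exactly onto the
#' homogeneous one-pool model), runs the homogeneous-vs-implicit nested
#' F-test on each, and reports the rejection rate at the nominal level.
#' Fits are warm-started at the generating truth and cross-seeded between
#' the two variants so that the nesting inequality holds at every optimum;
#' for a null-distribution study this is legitimate (the question is the
#' statistic's distribution at the optimum, not whether the optimum can be
#' found blind).
#'
#' @param n_replicates Number of synthetic studies.
#' @param seed Master seed.
#' @param truth Ground truth list as for [generate_study()]; default is a
#'   homogeneous variant of [default_truth()] with bulk replacement
#'   0.0133 per day.
#' @param design A [study_design()] object.
#' @param n_starts Cold starts per fit in addition to the warm starts.
#' @param alpha Nominal test level.
#' @return A list with `p_values`, `rejection_rate`, `alpha`, `n_replicates`.
#' @export
homogeneity_type1_experiment <- function(n_replicates = 1000, seed = 1,
                                         truth = NULL,
                                         design = study_design(),
                                         n_starts = 3, alpha = 0.05) {
  if (is.null(truth)) {
    truth <- default_truth()
    truth$kinetics <- explicit_params(p_n = 5e-4, f = 0.5,
                                      p_s1 = 0.01, d_s1 = 0.0133,
                                      p_s2 = 0.01, d_s2 = 0.0133,
                                      k = 2, Delta = 1e-5)
  }
  agg <- collapse_explicit(truth$kinetics)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_replicates)
  warm_h <- list(p_n = agg$p_n, p_s = agg$p_s, delta_ratio = agg$delta_ratio,
                 C = truth$telomere$C)
  pv <- vapply(seq_len(n_replicates), function(i) {
    st <- generate_study(truth, design, seed = rep_seeds[i])
    fd <- study_subset(st, lineage = "CD8", water = "truth")
    cfg_h <- fit_config(variant = "homogeneous", k = truth$kinetics$k,
                        n_starts = n_starts, seed = rep_seeds[i])
    cfg_i <- fit_config(variant = "implicit", k = truth$kinetics$k,
                        n_starts = n_starts, seed = rep_seeds[i])
    fh <- fit_model(fd, cfg_h, extra_starts = list(warm_h))
    eh <- as.list(fh$estimates)
    fi <- fit_model(fd, cfg_i, extra_starts = list(
      c(eh, list(ds_star = fh$kinetics$ds_star))
    ))
    ei <- as.list(fi$estimates)
    fh2 <- fit_model(fd, cfg_h, extra_starts = list(
      eh, ei[setdiff(names(ei), "ds_star")]
    ))
    ssr_h <- min(fh$ssr, fh2$ssr)
    f_test_nested(max(ssr_h, fi$ssr), min(fi$ssr, ssr_h),
                  fh$n_points, fh$n_par, fi$n_par)$p_value
  }, numeric(1))
  list(p_values = pv, rejection_rate = mean(pv < alpha), alpha = alpha,
       n_replicates = n_replicates)
}

#' Power of the homogeneity test against a two-subpopulation truth
#'
#' Generates replicate studies from a kinetically heterogeneous ground truth
#' (by default the reference truth with subpopulation half-lives 0.41 and
#' 8.74 years) and runs [test_homogeneity()] on each.
#'
#' @inheritParams homogeneity_type1_experiment
#' @param truth Heterogeneous ground truth; default [default_truth()].
#' @return A list with `p_values`, `rejection_rate`, `median_p`, `pooled`
#'   (Fisher combination across replicates).
#' @export
homogeneity_power_experiment <- function(n_replicates = 25, seed = 1,
                                         truth = default_truth(),
                                         design = study_design(),
                                         n_starts = 8, alpha = 0.05) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_replicates)
  pv <- vapply(seq_len(n_replicates), function(i) {
    st <- generate_study(truth, design, seed = rep_seeds[i])
    fd <- study_subset(st, lineage = "CD8", water = "truth")
    cfg <- fit_config(k = truth$kinetics$k, n_starts = n_starts,
                      seed = rep_seeds[i])
    test_homogeneity(fd, cfg)$test$p_value
  }, numeric(1))
  list(p_values = pv, rejection_rate = mean(pv < alpha),
       median_p = median(pv), pooled = pool_pvalues(pv))
}

#' Bootstrap confidence-interval coverage experiment
#'
#' Replicates the loop "generate a study, fit the one-pool implicit model,
#' build parametric-bootstrap percentile intervals, check whether they cover
#' the generating truth", reporting per-quantity coverage at the nominal
#' level.
#'
#' @inheritParams homogeneity_type1_experiment
#' @param truth Ground truth (default: the homogeneous reference truth, for
#'   which the implicit model is exactly correctly specified with
#'   `ds_star = d_s`).
#' @param B Bootstrap replicates per interval.
#' @param quantities Names of estimates/derived quantities to score.
#' @return A list with `coverage` (named rates), `n_replicates`, `B` and the
#'   per-replicate logical matrix `covered`.
#' @export
ci_coverage_experiment <- function(n_replicates = 150, seed = 1,
                                   truth = NULL, design = study_design(),
                                   B = 99, n_starts = 3,
                                   quantities = c("half_life_years",
                                                  "fraction_from_naive",
                                                  "p_s")) {
  if (is.null(truth)) {
    truth <- default_truth()
    truth$kinetics <- explicit_params(p_n = 5e-4, f = 0.5,
                                      p_s1 = 0.01, d_s1 = 0.0133,
                                      p_s2 = 0.01, d_s2 = 0.0133,
                                      k = 2, Delta = 1e-5)
    # C and delta_ratio are confounded through the single telomere point,
    # so the coverage study pins telomerase compensation at its true value
    truth$telomere <- telomere_params(delta_bp = 50, C = 0)
  }
  agg <- collapse_explicit(truth$kinetics)
  truth_vals <- c(p_n = agg$p_n, p_s = agg$p_s,
                  delta_ratio = agg$delta_ratio, ds_star = agg$ds_star,
                  half_life_years = clonal_half_life(agg$d_s, agg$p_s) / DAYS_PER_YEAR,
                  fraction_from_naive = derived_bulk_rates(agg)$fraction_from_naive)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_replicates)
  warm <- list(p_n = agg$p_n, p_s = agg$p_s, delta_ratio = agg$delta_ratio,
               ds_star = agg$ds_star)
  if (truth$telomere$C > 0) warm$C <- truth$telomere$C
  covered <- matrix(NA, n_replicates, length(quantities),
                    dimnames = list(NULL, quantities))
  for (i in seq_len(n_replicates)) {
    st <- generate_study(truth, design, seed = rep_seeds[i])
    fd <- study_subset(st, lineage = "CD8", water = "truth")
    cfg <- fit_config(variant = "implicit", k = truth$kinetics$k,
                      n_starts = n_starts, seed = rep_seeds[i],
                      C_mode = if (truth$telomere$C == 0) "zero" else "free")
    fit <- fit_model(fd, cfg, extra_starts = list(warm))
    set.seed(rep_seeds[i] %% 1000000L + 7L)
    ci <- confidence_intervals(fit, B = B)
    for (q in quantities) {
      row <- ci[ci$term == q, ]
      if (nrow(row) == 1L) {
        covered[i, q] <- truth_vals[[q]] >= row$conf.low &&
          truth_vals[[q]] <= row$conf.high
      }
    }
  }
  list(coverage = colMeans(covered, na.rm = TRUE),
       n_replicates = n_replicates, B = B, covered = covered)
}
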