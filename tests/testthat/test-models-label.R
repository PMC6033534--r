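test_that("naive fraction follows the closed form under constant label availability", {
  # constant U: baseline equal to plateau, cessation beyond the horizon
  bw <- bw_constant(u = 0.1)
  pars <- implicit_params(p_n = 0.01, p_s = 0, delta_ratio = 0, k = 0,
                          ds_star = 1)
  sol <- solve_label_implicit(pars, bw, c(50, 100))
  # F_TN(t) = c u (1 - e^{-p_n t})
  expect_equal(sol$F_TN, 0.1 * (1 - exp(-0.01 * c(50, 100))), tolerance = 1e-10)
  expect_equal(sol$F_TN[2], 0.0632121, tolerance = 1e-6)
})

test_that("no label influx means no labelled DNA anywhere", {
  bw <- bw_default()
  pars <- implicit_params(p_n = 0, p_s = 0, delta_ratio = 0, k = 3,
                          ds_star = 0.05)
  sol <- solve_label_implicit(pars, bw, seq(0, 300, by = 25))
  expect_true(all(sol$F_TN == 0))
  expect_true(all(sol$F_TSCM == 0))
})

test_that("homogeneous TSCM fraction saturates at c*u under constant availability", {
  bw <- bw_constant(u = 0.08, tau = 1e5)
  pars <- implicit_params(p_n = 0.01, p_s = 0.01, delta_ratio = 0.01, k = 2,
                          c = 1.5)
  sol <- solve_label_implicit(pars, bw, c(2000, 5000))
  expect_equal(sol$F_TSCM[2], 1.5 * 0.08, tolerance = 1e-6)
})

test_that("analytic solution matches lsoda and the fixed-step Euler oracle", {
  set.seed(21)
  bw <- bw_default()
  tt <- c(7, 21, 49, 70, 120, 200, 301)
  for (i in 1:10) {
    pars <- random_implicit()
    a <- solve_label_implicit(pars, bw, tt)
    b <- solve_label_implicit(pars, bw, tt, method = "lsoda")
    expect_equal(a$F_TSCM, b$F_TSCM, tolerance = 1e-6)
    expect_equal(a$F_TN, b$F_TN, tolerance = 1e-6)
    e <- tscmdyn:::euler_label_implicit_cpp(pars$p_n, pars$dn_loss, pars$p_s,
                                  pars$ds_star, pars$delta_ratio, pars$k,
                                  pars$c, bw$f_r, bw$delta_w, bw$beta_s,
                                  bw$tau, tt, 1e-3)
    expect_equal(a$F_TSCM, unname(e[, "F_TSCM"]), tolerance = 1e-4)
  }
  for (i in 1:5) {
    pars <- random_explicit()
    a <- solve_label_explicit(pars, bw, tt)
    b <- solve_label_explicit(pars, bw, tt, method = "lsoda")
    expect_equal(a$F_TSCM, b$F_TSCM, tolerance = 1e-6)
    e <- tscmdyn:::euler_label_explicit_cpp(pars$p_n, pars$dn_loss, pars$p_s1,
                                  pars$d_s1, pars$p_s2, pars$d_s2,
                                  pars$a1, pars$a2, pars$k, pars$c,
                                  bw$f_r, bw$delta_w, bw$beta_s, bw$tau,
                                  tt, 1e-3)
    expect_equal(a$F_TSCM1, unname(e[, "F_TSCM1"]), tolerance = 1e-4)
    expect_equal(a$F_TSCM2, unname(e[, "F_TSCM2"]), tolerance = 1e-4)
  }
})

test_that("identical subpopulations collapse the explicit model onto the one-pool model", {
  bw <- bw_default()
  tt <- seq(5, 300, by = 15)
  for (f in c(0.1, 0.5, 0.9)) {
    ep <- explicit_params(p_n = 5e-4, f = f, p_s1 = 0.01, d_s1 = 0.02,
                          p_s2 = 0.01, d_s2 = 0.02, k = 2)
    xe <- solve_label_explicit(ep, bw, tt)
    xi <- solve_label_implicit(collapse_explicit(ep), bw, tt)
    expect_equal(xe$F_TSCM, xi$F_TSCM, tolerance = 1e-6)
  }
})

test_that("explicit model degenerates continuously as f approaches 0 or 1", {
  bw <- bw_default()
  tt <- seq(5, 300, by = 25)
  base <- explicit_default()
  # f -> 0: bulk observable approaches the fast single-pool model
  lo <- explicit_params(p_n = base$p_n, f = 1e-8, p_s1 = base$p_s1,
                        d_s1 = base$d_s1, p_s2 = base$p_s2, d_s2 = base$d_s2,
                        k = base$k)
  fast_only <- implicit_params(p_n = base$p_n, p_s = base$p_s1,
                               delta_ratio = (base$d_s1 - base$p_s1) / 2^base$k,
                               k = base$k, ds_star = base$d_s1)
  expect_equal(solve_label_explicit(lo, bw, tt)$F_TSCM,
               solve_label_implicit(fast_only, bw, tt)$F_TSCM,
               tolerance = 1e-5)
  # f -> 1: the slow subpopulation is the whole gate
  hi <- explicit_params(p_n = base$p_n, f = 1 - 1e-8, p_s1 = base$p_s1,
                        d_s1 = base$d_s1, p_s2 = base$p_s2, d_s2 = base$d_s2,
                        k = base$k)
  sol_hi <- solve_label_explicit(hi, bw, tt)
  expect_equal(sol_hi$F_TSCM, sol_hi$F_TSCM2, tolerance = 1e-5)
})

test_that("predicted fractions are bounded by the scaled water plateau", {
  set.seed(31)
  bw <- bw_default()
  tt <- seq(0, 400, by = 10)
  for (i in 1:15) {
    ep <- random_explicit()
    sol <- solve_label_explicit(ep, bw, tt)
    expect_true(all(sol$F_TN >= -1e-12))
    expect_true(all(sol$F_TSCM <= ep$c * bw$f_r + 1e-10))
    hp <- implicit_params(p_n = 10^runif(1, -4, -2),
                          p_s = 10^runif(1, -3, -1.5),
                          delta_ratio = 10^runif(1, -4, -2.5),
                          k = sample(0:6, 1))   # homogeneous: ds_star derived
    sh <- solve_label_implicit(hp, bw, tt)
    expect_true(all(sh$F_TSCM >= -1e-12 & sh$F_TSCM <= hp$c * bw$f_r + 1e-10))
  }
})

test_that("derived bulk rates partition the TSCM input correctly", {
  p0 <- implicit_params(p_n = 1e-3, p_s = 0.01, delta_ratio = 0, k = 4)
  expect_equal(derived_bulk_rates(p0)$fraction_from_naive, 0)
  p1 <- implicit_params(p_n = 1e-3, p_s = 0, delta_ratio = 1e-3, k = 4)
  expect_equal(derived_bulk_rates(p1)$fraction_from_naive, 1)
  # symmetric case: naive influx equals self-renewal
  p2 <- implicit_params(p_n = 1e-3, p_s = 0.016, delta_ratio = 1e-3, k = 4)
  expect_equal(derived_bulk_rates(p2)$fraction_from_naive, 0.5)
  expect_equal(p2$d_s, 0.032)
})

test_that("solver input validation catches bad times and parameters", {
  bw <- bw_default()
  pars <- implicit_default()
  expect_error(solve_label_implicit(pars, bw, c(-1, 5)), "non-negative")
  expect_error(solve_label_implicit(pars, bw, c(5, 3)), "ascending")
  expect_error(explicit_params(p_n = 1e-4, f = 0.1, p_s1 = 0.02, d_s1 = 0.01,
                               p_s2 = 0.001, d_s2 = 0.002, k = 2),
               "d_si > p_si")
  expect_error(implicit_params(p_n = 1e-4, p_s = 0.01, delta_ratio = 1e-3,
                               k = 25), "between 0 and 20")
})
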