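test_that("steady-state theta follows the closed form", {
  telo0 <- telomere_params(delta_bp = 50, C = 0)
  # balanced proliferation: no divisional excess
  pb <- implicit_params(p_n = 0.01, p_s = 0.01, delta_ratio = 1e-3, k = 1)
  expect_equal(theta_steady_state(pb, telo0), 0)
  # hand-evaluated point
  p1 <- implicit_params(p_n = 0.0005, p_s = 0.01, delta_ratio = 0.001, k = 1)
  expect_equal(theta_steady_state(p1, telo0), 475)
  # huge naive influx: theta collapses to the burst cost C * delta
  telo1 <- telomere_params(delta_bp = 50, C = 1)
  p2 <- implicit_params(p_n = 0.0005, p_s = 0.01, delta_ratio = 100, k = 1)
  expect_equal(theta_steady_state(p2, telo1), 50, tolerance = 1e-3)
  # zero influx: steady state undefined
  p3 <- implicit_params(p_n = 0.0005, p_s = 0.01, delta_ratio = 0, k = 1)
  expect_error(theta_steady_state(p3, telo0), "undefined")
  expect_error(theta_steady_state(p1, telomere_params(C = 3)), "exceed")
})

test_that("theta dynamics relax exponentially to the fixed point", {
  pars <- implicit_params(p_n = 0.0005, p_s = 0.008, delta_ratio = 0.002,
                          k = 2)
  telo <- telomere_params(delta_bp = 50, C = 1)
  star <- theta_steady_state(pars, telo)
  # starting at the fixed point stays there
  td <- theta_dynamics(pars, telo, t_span = seq(0, 500, by = 50),
                       theta0 = star)
  expect_true(all(abs(td$theta_bp - star) < 1e-9))
  # independent check: numerical integration of the linear theta equation
  rate <- 2^pars$k * pars$delta_ratio
  ode <- deSolve::lsoda(0, seq(0, 2000, by = 20), function(t, y, p) {
    list(2 * (pars$p_s - pars$p_n) * telo$delta_bp -
           rate * (y - telo$C * telo$delta_bp))
  }, parms = NULL, rtol = 1e-10, atol = 1e-10)
  td2 <- theta_dynamics(pars, telo, t_span = seq(0, 2000, by = 20))
  expect_equal(td2$theta_bp, unname(ode[, 2]), tolerance = 1e-6)
  expect_equal(attr(td2, "rate"), rate)
  expect_true(attr(theta_dynamics(pars, telo, seq(0, 5000, by = 100)),
                   "converged"))
  # long-time value agrees with the closed form
  expect_equal(td2$theta_bp[nrow(td2)], star, tolerance = 1e-6)
})

test_that("division-indexed compartment oracle reproduces the mean-division theta", {
  set.seed(41)
  times <- seq(0, 4000, by = 100)
  for (i in 1:6) {
    # draws constrained so the 200-class truncation keeps negligible tail
    # mass: modest divisional excess and mean naive divisions over the window
    p_n <- 10^runif(1, -4.3, -3.7)
    k <- sample(1:4, 1)
    nl_total <- 10^runif(1, log10(2e-3), log10(8e-3))  # 2^k * delta_ratio
    dr <- nl_total / 2^k
    p_s <- p_n + runif(1, 0.3, 3) * nl_total
    C <- sample(0:k, 1)
    pars <- implicit_params(p_n = p_n, p_s = p_s, delta_ratio = dr, k = k)
    telo <- telomere_params(delta_bp = 50, C = C)
    oracle <- theta_compartment_oracle(p_s, p_n, dr, k, C, 50, times)
    closed <- theta_dynamics(pars, telo, t_span = times)$theta_bp
    expect_equal(closed, oracle, tolerance = 1e-4)
  }
})

test_that("naive mean divisions grow linearly at rate 2 p_n", {
  pars <- implicit_params(p_n = 0.001, p_s = 0.01, delta_ratio = 0.001, k = 2)
  md <- mean_divisions(pars, telomere_params(C = 1), t_span = c(0, 100, 200))
  expect_equal(md$mu_TN, 2 * 0.001 * c(0, 100, 200))
})

test_that("explicit-model theta matches its collapsed and limiting forms", {
  telo <- telomere_params(delta_bp = 50, C = 1)
  # identical subpopulations equal the one-pool value
  ep <- explicit_params(p_n = 5e-4, f = 0.4, p_s1 = 0.01, d_s1 = 0.02,
                        p_s2 = 0.01, d_s2 = 0.02, k = 2)
  expect_equal(theta_explicit(ep, telo)$theta_bp,
               theta_steady_state(collapse_explicit(ep), telo))
  # f -> 1: only the slow subpopulation contributes
  base <- explicit_default()
  hi <- explicit_params(p_n = base$p_n, f = 1 - 1e-9, p_s1 = base$p_s1,
                        d_s1 = base$d_s1, p_s2 = base$p_s2, d_s2 = base$d_s2,
                        k = base$k)
  th <- theta_explicit(hi, telo)
  expect_equal(th$theta_bp, th$theta_2, tolerance = 1e-6)
})

test_that("explicit-model theta agrees with per-subpopulation compartment oracles", {
  set.seed(43)
  times <- seq(0, 20000, by = 500)
  for (i in 1:4) {
    p_n <- 10^runif(1, -4.8, -4.3)
    k <- sample(1:4, 1)
    nl1 <- 10^runif(1, log10(3e-3), log10(2e-2))
    nl2 <- 10^runif(1, log10(4e-4), log10(1e-3))
    p_s1 <- p_n + runif(1, 0.3, 3) * nl1
    p_s2 <- p_n + runif(1, 0.3, 3) * nl2
    ep <- explicit_params(p_n = p_n, f = runif(1, 0.05, 0.5),
                          p_s1 = p_s1, d_s1 = p_s1 + nl1,
                          p_s2 = p_s2, d_s2 = p_s2 + nl2, k = k)
    C <- sample(0:k, 1)
    telo <- telomere_params(delta_bp = 50, C = C)
    # each subpopulation is a stationary one-pool system with its own influx
    th1 <- theta_compartment_oracle(ep$p_s1, ep$p_n, ep$a1, ep$k, C, 50, times)
    th2 <- theta_compartment_oracle(ep$p_s2, ep$p_n, ep$a2, ep$k, C, 50, times)
    w2 <- ep$rel_size_slow
    bulk_oracle <- (1 - w2) * th1[length(times)] + w2 * th2[length(times)]
    expect_equal(theta_explicit(ep, telo)$theta_bp, bulk_oracle,
                 tolerance = 1e-3)
  }
})

test_that("theta responds monotonically to self-renewal, compensation and influx", {
  telo_grid <- function(p_s, C, dr) {
    theta_steady_state(
      implicit_params(p_n = 5e-4, p_s = p_s, delta_ratio = dr, k = 2),
      telomere_params(delta_bp = 50, C = C)
    )
  }
  ps_vals <- seq(0.002, 0.02, length.out = 8)
  expect_true(all(diff(sapply(ps_vals, telo_grid, C = 1, dr = 1e-3)) > 0))
  C_vals <- seq(0, 2, length.out = 8)
  expect_true(all(diff(sapply(C_vals, function(C) telo_grid(0.01, C, 1e-3))) > 0))
  dr_vals <- 10^seq(-4, -2, length.out = 8)
  expect_true(all(diff(sapply(dr_vals, function(d) telo_grid(0.01, 1, d))) < 0))
})
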