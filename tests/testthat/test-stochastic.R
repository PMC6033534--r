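test_that("deterministic clonal half-life and its inverse behave", {
  expect_equal(deterministic_half_life(d = log(2) / 365 + 0.01, p = 0.01), 365)
  expect_error(deterministic_half_life(d = 0.01, p = 0.01), "d > p")
  # a 9-year half-life corresponds to a tiny net loss rate
  expect_equal(net_loss_from_half_life(9), log(2) / (9 * 365.25))
  expect_equal(net_loss_from_half_life(9), 2.108e-4, tolerance = 1e-3)
  expect_equal(clonal_half_life(0.01, 0.02), Inf)
})

test_that("initial clone size follows the burst arithmetic", {
  expect_equal(initial_clone_size(k = 0, Delta = 1e-5, f = 1), 1e6)
  expect_equal(initial_clone_size(k = 10, Delta = 1e-5, f = 0.058), 59392000)
  expect_warning(n0 <- initial_clone_size(k = 5, Delta = 1e-5, f = 0),
                 "no long-lived clone")
  expect_equal(n0, 0)
})

test_that("pure-death clones die at the exponential rate", {
  cfg <- clone_sim_config(p = 0, d = 0.01, n0 = 1, n_runs = 10000, seed = 7)
  fates <- simulate_clone(cfg)
  se <- sd(fates$extinction_time_days) / sqrt(nrow(fates))
  expect_lt(abs(mean(fates$extinction_time_days) - 100), 3 * se)
  expect_false(any(fates$censored))
  # n0 = 2: expected extinction is the mean maximum of two exponentials
  cfg2 <- clone_sim_config(p = 0, d = 0.01, n0 = 2, n_runs = 8000, seed = 8)
  f2 <- simulate_clone(cfg2)
  se2 <- sd(f2$extinction_time_days) / sqrt(nrow(f2))
  expect_lt(abs(mean(f2$extinction_time_days) - 150), 3 * se2)
})

test_that("large-clone population half-life matches the deterministic value", {
  cfg <- clone_sim_config(p = 0.002, d = 0.004, n0 = 10000, n_runs = 400,
                          seed = 9, max_time = 5000)
  fates <- simulate_clone(cfg)
  target <- deterministic_half_life(0.004, 0.002)   # 346.6 days
  expect_lt(abs(median(fates$half_life_days) / target - 1), 0.05)
  # extinction can never precede the half-life
  ok <- !is.na(fates$extinction_time_days)
  expect_true(all(fates$extinction_time_days[ok] >= fates$half_life_days[ok]))
})

test_that("immortal clones are right-censored at the horizon", {
  cfg <- clone_sim_config(p = 0.05, d = 0, n0 = 5, n_runs = 20,
                          max_time = 200, seed = 3)
  fates <- simulate_clone(cfg)
  expect_true(all(fates$censored))
  expect_true(all(is.na(fates$extinction_time_days)))
})

test_that("mean simulated size tracks the deterministic exponential decline", {
  # compare E[x(t)] = n0 exp((p - d) t) at three checkpoints
  for (tchk in c(100, 250, 500)) {
    cfg <- clone_sim_config(p = 0.004, d = 0.01, n0 = 200, n_runs = 3000,
                            max_time = tchk, seed = 101)
    fates <- simulate_clone(cfg)
    expected <- 200 * exp((0.004 - 0.01) * tchk)
    se <- sd(fates$final_size) / sqrt(nrow(fates))
    expect_lt(abs(mean(fates$final_size) - expected), 4 * se + 1e-9)
  }
})

test_that("extinction probabilities match branching-process theory", {
  # subcritical: extinction is certain
  cfg <- clone_sim_config(p = 0.002, d = 0.01, n0 = 50, n_runs = 300,
                          max_time = 1e5, seed = 11)
  expect_true(all(!simulate_clone(cfg)$censored))
  # supercritical: extinction probability (d/p)^n0
  cfg2 <- clone_sim_config(p = 0.02, d = 0.01, n0 = 3, n_runs = 2000,
                           max_time = 800, seed = 12)
  f2 <- simulate_clone(cfg2)
  p_ext <- mean(!f2$censored)
  expect_lt(abs(p_ext - 0.5^3), 4 * sqrt(0.125 * 0.875 / 2000) + 0.01)
})

test_that("simulations are reproducible from the seed", {
  cfg <- clone_sim_config(p = 0.01, d = 0.02, n0 = 30, n_runs = 50, seed = 123)
  expect_identical(simulate_clone(cfg), simulate_clone(cfg))
  tr <- simulate_clone_trajectory(clone_sim_config(p = 0.01, d = 0.02,
                                                   n0 = 30, seed = 5))
  tr2 <- simulate_clone_trajectory(clone_sim_config(p = 0.01, d = 0.02,
                                                    n0 = 30, seed = 5))
  expect_identical(tr, tr2)
  expect_equal(tr$size[1], 30)
})

test_that("expected precursor lifespan approximates simulated extinction times", {
  # doubling the clone size adds about ln2 / (d - p) to the lifespan
  d <- 0.01; p <- 0.004
  s1 <- simulate_clone(clone_sim_config(p, d, n0 = 500, n_runs = 2000,
                                        seed = 21, max_time = 1e4))
  s2 <- simulate_clone(clone_sim_config(p, d, n0 = 1000, n_runs = 2000,
                                        seed = 22, max_time = 1e4))
  gap <- median(s2$extinction_time_days) - median(s1$extinction_time_days)
  expect_lt(abs(gap - log(2) / (d - p)), 25)
  # and the analytic approximation lands near the simulated mean
  expect_lt(abs(expected_precursor_lifespan(d, p, 500) /
                  mean(s1$extinction_time_days) - 1), 0.05)
})

test_that("degree of self-renewal equals the inverse net loss rate", {
  expect_equal(degree_of_self_renewal(list(d = 0.01 + 0.002, p = 0.002)), 100)
  expect_equal(degree_of_self_renewal(list(d = 0.001, p = 0.002)), Inf)
  # Table-style slow half-life of 8.74 years gives ~4600 days
  dsr <- degree_of_self_renewal(explicit_default(), "slow")
  expect_equal(dsr, 8.74 * 365.25 / log(2), tolerance = 1e-10)
  expect_equal(dsr, 4605, tolerance = 1e-3)
  # rate form and steady-state flux form agree on random draws
  set.seed(31)
  for (i in 1:20) {
    ep <- random_explicit()
    expect_equal(degree_of_self_renewal(ep, "slow"),
                 1 / (ep$a2 * 2^ep$k), tolerance = 1e-10)
    expect_equal(degree_of_self_renewal(ep, "fast"),
                 1 / (ep$d_s1 - ep$p_s1), tolerance = 1e-10)
  }
})

test_that("precursor lifespan distributions use the right seeding conventions", {
  ip <- implicit_params(p_n = 5e-4, p_s = 0.005, delta_ratio = 5e-3, k = 0,
                        Delta = 1e-8, ratio_NS = 5e5)
  res <- precursor_lifespan_distribution(ip, mode = "bulk", n_runs = 50,
                                         seed = 2)
  expect_equal(res$n0, 1000)
  expect_equal(nrow(res$fates), 50)
  ep <- explicit_default(k = 0, Delta = 1e-5)
  res2 <- precursor_lifespan_distribution(ep, mode = "long_lived",
                                          n_runs = 20, seed = 3)
  expect_equal(res2$n0, initial_clone_size(ep$k, 1e-5, ep$f))
  expect_true(all(res2$fates$extinction_time_days > 0 | res2$fates$censored))
  ep_nod <- explicit_default(Delta = NULL)
  expect_error(precursor_lifespan_distribution(ep_nod, mode = "long_lived"),
               "Delta")
})
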