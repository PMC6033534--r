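# Shared fixtures: small parameter sets and generators used across tests.

bw_default <- function() body_water_params(f_r = 0.05, delta_w = 0.1,
                                           beta_s = 0.01, tau = 49)

# A water curve that is constant over the evaluation window: baseline equal
# to plateau and cessation beyond the horizon.
bw_constant <- function(u = 0.1, tau = 1000) {
  body_water_params(f_r = u, delta_w = 0.1, beta_s = u, tau = tau)
}

implicit_default <- function(ds_star = 0.02) {
  implicit_params(p_n = 5e-4, p_s = 0.01, delta_ratio = 0.005, k = 2,
                  ds_star = ds_star)
}

explicit_default <- function(f = 0.058, k = 2, Delta = 1e-5) {
  explicit_params(
    p_n = 5e-4, f = f,
    p_s1 = 0.015, d_s1 = 0.015 + net_loss_from_half_life(0.41),
    p_s2 = 0.002, d_s2 = 0.002 + net_loss_from_half_life(8.74),
    k = k, Delta = Delta
  )
}

random_implicit <- function() {
  implicit_params(
    p_n = 10^runif(1, -4.5, -2.5),
    p_s = 10^runif(1, -3.5, -1.5),
    delta_ratio = 10^runif(1, -4.5, -2.5),
    k = sample(0:8, 1),
    ds_star = 10^runif(1, -3, -1)
  )
}

random_explicit <- function() {
  p_s1 <- 10^runif(1, -2.5, -1.5)
  p_s2 <- 10^runif(1, -3.5, -2.5)
  explicit_params(
    p_n = 10^runif(1, -4.5, -3),
    f = runif(1, 0.02, 0.5),
    p_s1 = p_s1, d_s1 = p_s1 + 10^runif(1, -2.6, -1.8),
    p_s2 = p_s2, d_s2 = p_s2 + 10^runif(1, -4, -3),
    k = sample(0:8, 1)
  )
}

# Division-indexed compartment oracle for the telomere model: integrates the
# per-division-class populations directly (brute force, deSolve), for a
# stationary naive/TSCM system, and returns delta_bp * (mu_TSCM - mu_TN)
# over time.  Independent of the closed-form theta machinery.
theta_compartment_oracle <- function(p_s, p_n, delta_ratio, k, C,
                                     delta_bp, times, n_classes = 200) {
  # Class fractions for stationary naive and TSCM pools.  Naive
  # stationarity (p_n = d_n + Delta) makes the class-fraction dynamics
  # dn_i = 2 p_n (n_{i-1} - n_i); TSCM stationarity fixes
  # d_s = 2^k * delta_ratio + p_s, under which the fractions stay
  # normalised automatically.
  d_s <- 2^k * delta_ratio + p_s
  nc <- n_classes
  deriv <- function(t, y, parms) {
    nN <- y[1:nc]
    nS <- y[nc + (1:nc)]
    shiftN <- c(0, nN[-nc])
    shiftS <- c(0, nS[-nc])
    dN <- 2 * p_n * (shiftN - nN)
    # TSCM class i receives naive class i - C (C burst divisions cost length)
    influx <- if (C > 0) c(rep(0, C), nN[seq_len(nc - C)]) else nN
    dS <- 2 * p_s * shiftS - (p_s + d_s) * nS + delta_ratio * 2^k * influx
    list(c(dN, dS))
  }
  y0 <- c(c(1, rep(0, nc - 1)), c(1, rep(0, nc - 1)))
  out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  idx <- 0:(nc - 1)
  sapply(seq_along(times), function(j) {
    nN <- out[j, 2:(nc + 1)]
    nS <- out[j, (nc + 2):(2 * nc + 1)]
    tail_mass <- (nN[nc] + nS[nc]) / (sum(nN) + sum(nS))
    stopifnot(tail_mass < 1e-9)
    delta_bp * (sum(idx * nS) / sum(nS) - sum(idx * nN) / sum(nN))
  })
}
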