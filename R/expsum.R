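# Exponential-sum representation of functions f(t) = sum_i coef_i * exp(rate_i * t).
#
# The label-kinetics ODEs are linear with forcing terms that are themselves
# sums of exponentials (the body-water curve U(t) is piecewise exponential,
# and each state feeds the next through linear terms), so every state variable
# has an exact solution in this family.  Solving in this representation is
# exact up to floating point and orders of magnitude faster than numerical
# integration, which matters for the multi-start fits and bootstrap loops.

es_new <- function(coef, rate) {
  stopifnot(length(coef) == length(rate))
  list(coef = as.numeric(coef), rate = as.numeric(rate))
}

es_zero <- function() es_new(numeric(0), numeric(0))

es_scale <- function(a, s) es_new(a$coef * s, a$rate)

es_add <- function(a, b) {
  rate <- c(a$rate, b$rate)
  coef <- c(a$coef, b$coef)
  if (anyDuplicated(rate)) {
    coef <- as.numeric(tapply(coef, rate, sum))
    rate <- sort(unique(rate))
    # tapply sorts by the grouping values, so coef is aligned with sorted rate
  }
  es_new(coef, rate)
}

es_eval <- function(a, t) {
  if (length(a$coef) == 0L) return(rep(0, length(t)))
  drop(exp(outer(t, a$rate)) %*% a$coef)
}

# Exact solution of y'(t) = -lambda * y + f(t) with f an exponential sum and
# y(t0) = y0, returned as an exponential sum in absolute time, valid t >= t0.
# Resonant terms (rate_i == -lambda) are handled by nudging the denominator,
# equivalent to perturbing that forcing coefficient by a ~1e-9 relative amount;
# this keeps the solution family free of t*exp(rate*t) terms.
es_solve_linear <- function(lambda, forcing, y0, t0) {
  denom <- lambda + forcing$rate
  if (length(denom)) {
    eps <- 1e-9 * pmax(abs(lambda) + abs(forcing$rate), 1e-12)
    small <- abs(denom) < eps
    denom[small] <- ifelse(denom[small] >= 0, eps[small], -eps[small])
  }
  part <- es_new(forcing$coef / denom, forcing$rate)
  k0 <- (y0 - es_eval(part, t0)) * exp(lambda * t0)
  es_add(part, es_new(k0, -lambda))
}

# A piecewise exponential-sum function: list of pieces, each with a start time
# and an es; evaluation picks the piece whose interval contains t.
pes_new <- function(breaks, pieces) {
  stopifnot(length(pieces) == length(breaks))
  structure(list(breaks = breaks, pieces = pieces), class = "tscm_pes")
}

pes_eval <- function(p, t) {
  idx <- findInterval(t, p$breaks)
  idx[idx < 1L] <- 1L
  out <- numeric(length(t))
  for (i in unique(idx)) {
    sel <- idx == i
    out[sel] <- es_eval(p$pieces[[i]], t[sel])
  }
  out
}
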