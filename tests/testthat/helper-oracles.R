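# Independent oracles used across the suite.

# Mann-Whitney U of x vs y by direct pair counting (ties count 1/2)
u_by_pair_counting <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exact permutation distribution of U_x for small pooled samples
u_permutation_distribution <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  picks <- utils::combn(length(pooled), n1)
  apply(picks, 2, function(ix)
    u_by_pair_counting(pooled[ix], pooled[-ix]))
}

# closed-form membrane relaxation for a leak-only cell: from V0 towards VL
# with time constant C/gL
leak_relaxation <- function(t, V0, VL, gL, C) {
  VL + (V0 - VL) * exp(-t * gL / C)
}

# a synthetic square-pulse voltage trace on a uniform grid
square_trace <- function(t_total = 500, dt = 0.5, rest = -65,
                         pulses = list(c(100, 350, 40))) {
  tt <- seq(0, t_total, by = dt)
  V <- rep(rest, length(tt))
  for (p in pulses) V[tt >= p[1] & tt < p[2]] <- p[3]
  structure(data.frame(t = tt, V = V), dt_out = dt)
}

# short-protocol parameters used by simulation tests
quick_protocol <- function(params, t_total = 1200, ...) {
  simulate_model(params, feeding_schedule(t_total = t_total, params = params),
                 ...)
}
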