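# Independent oracles used to cross-check the implementation.

# Direct trapezoidal evaluation of the hereditary integral
# eps(t) = int_0^t G(t - s) dW/ds ds, O(n^2); the reference for the
# recursive Prony update.
qlv_trapezoid_oracle <- function(W, params, fs) {
  n <- length(W)
  dt <- 1 / fs
  G <- function(t) params$g_inf +
    params$prony_g1 * exp(-t / params$prony_tau1) +
    params$prony_g2 * exp(-t / params$prony_tau2)
  dWdt <- c(0, diff(W)) / dt
  out <- numeric(n)
  for (k in seq_len(n)) {
    if (k == 1) { out[1] <- W[1]; next }
    s <- (seq_len(k) - 1) * dt
    integrand <- G((k - 1) * dt - s) * dWdt[seq_len(k)]
    out[k] <- sum((integrand[-1] + integrand[-k]) / 2) * dt
  }
  out
}

# Event-based simulation of the LIF array under constant per-zone drives:
# after each reset every zone charges from 0 towards R*I_z; the first zone
# to reach threshold wins and resets all.  Exact continuous-time solution.
lif_event_oracle <- function(I, params, t_max) {
  R <- params$resistance
  times <- numeric(0)
  zones <- integer(0)
  t <- 0
  repeat {
    tt <- ifelse(R * I > params$threshold,
                 params$tau * log(R * I / (R * I - params$threshold)), Inf)
    if (all(!is.finite(tt))) break
    z <- which.min(tt)
    t <- t + params$refractory + tt[z]
    if (t > t_max) break
    times <- c(times, t)
    zones <- c(zones, z)
  }
  list(time_ms = times, zone = zones)
}

# Closed-form OLS slope of y against 1..n.
ols_slope_oracle <- function(y) {
  x <- seq_along(y)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# All partitions of `total` units into `k` positive parts (descending).
enumerate_partitions <- function(total, k) {
  if (k == 1) return(list(total))
  out <- list()
  for (first in ceiling(total / k):(total - k + 1)) {
    for (rest in enumerate_partitions(total - first, k - 1)) {
      if (max(rest) <= first) out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}
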