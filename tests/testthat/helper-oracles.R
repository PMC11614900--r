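# Independent oracles used across the suite. They deliberately avoid the
# package's propagator machinery.

# Closed-form product-operator evolution of a weakly coupled two-spin pair
# under 2*pi*J Iz Sz: Ix -> Ix cos(pi J t) + 2 Iy Sz sin(pi J t).
oracle_zz_ix <- function(J, t) {
  c(ix = cos(pi * J * t), iysz = sin(pi * J * t))
}

# Fine-step Euler integration of dM/dt = L M (integrator oracle).
oracle_euler <- function(L, m0, t_end, n_steps = 2e5) {
  dt <- t_end / n_steps
  m <- m0
  for (i in seq_len(n_steps)) m <- m + dt * (L %*% m)
  as.numeric(m)
}

# Brute-force 2-D grid minimization of the weighted Eyring SSE in (dH, dS).
oracle_eyring_grid <- function(tab, dH_range, dS_range, n = 61) {
  dHs <- seq(dH_range[1], dH_range[2], length.out = n)
  dSs <- seq(dS_range[1], dS_range[2], length.out = n)
  w <- (tab$kd_per_s / tab$sigma_kd)^2
  best <- c(NA, NA, Inf)
  for (dH in dHs) for (dS in dSs) {
    pred <- log(eyring_rate(tab$temperature_K, dH, dS) / tab$temperature_K)
    sse <- sum(w * (log(tab$kd_per_s / tab$temperature_K) - pred)^2)
    if (sse < best[3]) best <- c(dH, dS, sse)
  }
  best
}

# Random kinetics data set truth used by parameterised recovery tests.
recovery_cases <- tidyr::expand_grid(
  k_d = c(1, 3, 8, 25),
  ratio = c(0.05, 0.1, 0.5)
)
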