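# Shared fixtures and independent oracles used across the test files.

# Constant-rotation trajectory built directly on the fine grid.
const_rotation_traj <- function(omega_rad_s, duration_ms, dt = 1) {
  t <- seq(0, duration_ms, by = dt)
  hdspeed:::new_trajectory(t, omega_rad_s * t / 1000, dt, "synthetic")
}

# Constant-heading trajectory.
const_heading_traj <- function(theta0, duration_ms, dt = 1) {
  t <- seq(0, duration_ms, by = dt)
  hdspeed:::new_trajectory(t, rep(theta0, length(t)), dt, "synthetic")
}

# Event-driven TM state (x, u, g) sampled at given times (pre-jump at any
# time that coincides with a spike). This is the implementation path.
tm_states_on_grid <- function(spikes, params, t_grid) {
  st <- tm_state()
  ev <- c(as.numeric(spikes), Inf)
  j <- 1L
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = 3L,
                dimnames = list(NULL, c("x", "u", "g")))
  for (i in seq_along(t_grid)) {
    t <- t_grid[i]
    while (ev[j] < t) {
      st <- tm_relax(st, ev[j] - st$t_last, params)
      st <- tm_spike(st, params)$state
      j <- j + 1L
    }
    tmp <- tm_relax(st, t - st$t_last, params)
    out[i, ] <- c(tmp$x, tmp$u, tmp$g)
  }
  out
}

# Brute-force oracle: classical RK4 at a fixed step on the between-spike
# linear ODEs, with the jump relations applied exactly at spike steps.
# Vectorized over many trains (spike times must lie on the dt_ode grid).
# Returns list of matrices (one per train) with states at record_steps
# (recorded before any jump scheduled at that step).
tm_rk4_oracle <- function(spike_steps, params, n_steps, dt_ode,
                          record_steps) {
  nt <- length(spike_steps)
  x <- rep(1, nt); u <- numeric(nt); g <- numeric(nt)
  p <- params
  # map step -> train indices spiking at that step
  all_tr <- rep(seq_len(nt), lengths(spike_steps))
  all_st <- unlist(spike_steps, use.names = FALSE)
  spike_map <- split(all_tr, all_st)
  rec <- array(NA_real_, dim = c(nt, length(record_steps), 3L))
  rec_i <- 1L
  rec_set <- record_steps
  deriv <- function(x, u, g) {
    list(dx = (1 - x) / p$tau_d, du = -u / p$tau_f, dg = -g / p$tau_g)
  }
  for (s in seq_len(n_steps)) {
    if (rec_i <= length(rec_set) && rec_set[rec_i] == s - 1L) {
      rec[, rec_i, ] <- cbind(x, u, g)
      rec_i <- rec_i + 1L
    }
    tr <- spike_map[[as.character(s - 1L)]]
    if (!is.null(tr)) {
      up <- u[tr] + p$U * (1 - u[tr])
      rel <- up * x[tr]
      g[tr] <- g[tr] + p$weight * rel
      x[tr] <- x[tr] * (1 - up)
      u[tr] <- up
    }
    k1 <- deriv(x, u, g)
    k2 <- deriv(x + dt_ode / 2 * k1$dx, u + dt_ode / 2 * k1$du,
                g + dt_ode / 2 * k1$dg)
    k3 <- deriv(x + dt_ode / 2 * k2$dx, u + dt_ode / 2 * k2$du,
                g + dt_ode / 2 * k2$dg)
    k4 <- deriv(x + dt_ode * k3$dx, u + dt_ode * k3$du, g + dt_ode * k3$dg)
    x <- x + dt_ode / 6 * (k1$dx + 2 * k2$dx + 2 * k3$dx + k4$dx)
    u <- u + dt_ode / 6 * (k1$du + 2 * k2$du + 2 * k3$du + k4$du)
    g <- g + dt_ode / 6 * (k1$dg + 2 * k2$dg + 2 * k3$dg + k4$dg)
  }
  if (rec_i <= length(rec_set) && rec_set[rec_i] == n_steps) {
    rec[, rec_i, ] <- cbind(x, u, g)
  }
  rec
}

# Plug-in entropy (bits) of an equal-width binning, for MI identities.
binned_entropy <- function(x, bins) {
  xi <- hdspeed:::bin_series(x, bins)
  p <- tabulate(xi, nbins = bins) / length(xi)
  p <- p[p > 0]
  -sum(p * log2(p))
}
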