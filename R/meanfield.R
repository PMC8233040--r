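# Mean-field reduction of the circuit: the stochastic spiking ensemble is
# replaced by a continuum of preferred angles carrying a depression field
# x(theta, t),
#   dx/dt = (1 - x)/tau_d - U * x * f(theta - theta_A(t)),
# whose release-weighted drive D(t) = integral of U * x * f over the
# circle feeds a first-order postsynaptic integrator. Facilitation is
# dropped: at the fitted synapse tau_f << tau_d, so depression dominates.

#' Mean-field model parameters
#'
#' @param resolution number of grid points over `[0, 2*pi)` (>= 64).
#' @param f_bg,f_max,epsilon shared tuning-curve parameters (Hz, Hz,
#'   dimensionless); representative single-cell values rather than a
#'   distribution, since the continuum carries no cell heterogeneity.
#' @param tau_d depression recovery time, ms.
#' @param U baseline release fraction.
#' @param tau_post postsynaptic integration time constant, ms.
#' @param ati anticipatory time interval, ms.
#' @return A `meanfield_params` object.
#' @export
meanfield_params <- function(resolution = 256L, f_bg = 3, f_max = 60,
                             epsilon = 4, tau_d = 270, U = 0.28,
                             tau_post = 10, ati = 0) {
  if (resolution < 64L) stop("`resolution` must be >= 64", call. = FALSE)
  # aliasing guard: the tuning curve's angular width ~ 1/sqrt(epsilon)
  # must be resolved by several grid cells
  if (2 * pi / resolution > 0.25 / sqrt(epsilon)) {
    stop("`resolution` too coarse for this tuning width", call. = FALSE)
  }
  stopifnot_scalar_pos(tau_d, "tau_d")
  stopifnot_scalar_pos(tau_post, "tau_post")
  structure(list(resolution = as.integer(resolution), f_bg = f_bg,
                 f_max = f_max, epsilon = epsilon, tau_d = tau_d, U = U,
                 tau_post = tau_post, ati = ati),
            class = "meanfield_params")
}

#' Simulate the mean-field depression field along a trajectory
#'
#' Operator splitting per time step with exact sub-flows: the depletion
#' factor `exp(-U f dt)` is applied first, then the exact linear
#' relaxation toward 1 with `tau_d`. The drive is
#' `D(t) = sum_j U x_j f_j dtheta` and the postsynaptic rate is its
#' first-order low-pass with `tau_post`.
#'
#' @param traj an `hd_trajectory`.
#' @param params a [meanfield_params()].
#' @return List with `t`, `drive`, `rate` (low-passed drive) and `x_final`
#'   (the depression field at the last step).
#' @export
simulate_meanfield <- function(traj, params = meanfield_params()) {
  stopifnot(inherits(traj, "hd_trajectory"))
  p <- params
  dtheta <- 2 * pi / p$resolution
  grid <- (seq_len(p$resolution) - 1L) * dtheta
  av <- angular_velocity(traj)
  theta_eff <- traj$theta + p$ati / 1000 * av$omega
  dt <- traj$dt
  n <- length(theta_eff)
  x <- rep(1, p$resolution)
  drive <- numeric(n)
  ed <- exp(-dt / p$tau_d)
  for (i in seq_len(n)) {
    f <- tuning_curve(grid - theta_eff[i], p$f_bg, p$f_max, p$epsilon)
    f_ms <- f / 1000                      # Hz -> events per ms
    drive[i] <- p$U * sum(x * f) * dtheta
    x <- x * exp(-p$U * f_ms * dt)        # depletion sub-flow (exact)
    x <- 1 - (1 - x) * ed                 # recovery sub-flow (exact)
  }
  rate <- rate_readout(drive, dt, tau_m = p$tau_post, rectify = FALSE)
  list(t = traj$t, drive = drive, rate = rate, x_final = x)
}

#' Steady mean-field drive at constant rotation speeds
#'
#' For each rotation speed the head angle advances linearly and the field
#' is integrated to its rotating steady state; the reported drive is the
#' average over the final fifth of the run. A log-log regression of
#' `D(omega) - D(0)` on `omega` gives the low-speed scaling exponent,
#' which the depression mechanism predicts to be 2 (quadratic).
#'
#' @param params a [meanfield_params()].
#' @param omegas rotation speeds, rad/s (> 0).
#' @param duration_s integration time per speed, seconds.
#' @param dt time step, ms.
#' @return List with `omega`, `drive`, `drive_rest` (the `omega = 0`
#'   fixed point), `exponent` (fitted log-log slope) and `concave_up`
#'   (positive second differences of drive vs omega).
#' @export
speed_scaling <- function(params = meanfield_params(),
                          omegas = seq(0.1, 0.5, by = 0.1),
                          duration_s = 3, dt = 1) {
  if (!length(omegas) || any(omegas <= 0)) {
    stop("`omegas` must be positive", call. = FALSE)
  }
  if (length(omegas) < 3L) {
    stop("need at least 3 speeds for the scaling fit", call. = FALSE)
  }
  omegas <- sort(omegas)
  steady <- function(om) {
    nt <- round(duration_s * 1000 / dt) + 1L
    t <- (seq_len(nt) - 1L) * dt
    traj <- new_trajectory(t, om * t / 1000, dt, "synthetic")
    sim <- simulate_meanfield(traj, params)
    tail_idx <- t >= duration_s * 1000 * 0.8
    mean(sim$drive[tail_idx])
  }
  d0 <- steady(1e-9)   # rest fixed point via a vanishing rotation
  dd <- vapply(omegas, steady, numeric(1))
  excess <- dd - d0
  if (any(excess <= 0)) {
    stop("drive excess not positive; speeds outside the depression regime",
         call. = FALSE)
  }
  fit <- stats::lm(log(excess) ~ log(omegas))
  second_diff <- diff(diff(dd) / diff(omegas)) / diff(omegas[-1L])
  list(omega = omegas, drive = dd, drive_rest = d0,
       exponent = unname(stats::coef(fit)[2L]),
       concave_up = all(diff(dd, differences = 2L) > 0))
}

#' ATI compensation of the postsynaptic integration lag (mean-field)
#'
#' For each fixed ATI, simulates the mean-field rate along a trajectory
#' and extracts the optimal lag of its correlation with angular head
#' speed. Anticipation shifts the optimal lag toward zero, compensating
#' the delay introduced by synaptic and postsynaptic integration.
#'
#' @param params a [meanfield_params()].
#' @param ati_values ATI values, ms.
#' @param traj an `hd_trajectory` (e.g. from [ou_trajectory()]).
#' @param lags lag grid, ms.
#' @return Data frame with `ati_ms`, `optimal_lag_ms`, `max_corr`; the
#'   attribute `best_ati` is the ATI minimizing `|optimal_lag|`.
#' @export
ati_lag_compensation <- function(params = meanfield_params(), ati_values,
                                 traj, lags = seq(-70, 70, by = 2)) {
  av <- angular_velocity(traj)
  rows <- lapply(ati_values, function(a) {
    p <- params
    p$ati <- a
    sim <- simulate_meanfield(traj, p)
    corr <- lagged_correlation(sim$rate, av$speed, traj$dt, lags = lags)
    data.frame(ati_ms = a, optimal_lag_ms = corr$optimal_lag,
               max_corr = corr$max_value)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_ati") <- out$ati_ms[which.min(abs(out$optimal_lag_ms))]
  out
}
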