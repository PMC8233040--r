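# Head-direction trajectories: synthetic generation, loading of tracking
# tables, angular velocity, and the anticipatory (effective) trajectory.

new_trajectory <- function(t, theta, dt, meta) {
  structure(list(t = t, theta = theta, dt = dt, meta = meta),
            class = "hd_trajectory")
}

#' @export
print.hd_trajectory <- function(x, ...) {
  cat(sprintf(
    "<hd_trajectory> %d samples, dt = %g ms, duration = %.3f s (%s)\n",
    length(x$t), x$dt, (x$t[length(x$t)] - x$t[1L]) / 1000, x$meta))
  invisible(x)
}

#' @export
as.data.frame.hd_trajectory <- function(x, ...) {
  av <- angular_velocity(x)
  data.frame(t_ms = x$t, theta_rad = x$theta, omega_rad_s = av$omega)
}

#' Synthetic head-direction trajectory with Ornstein-Uhlenbeck velocity
#'
#' Generates a head-direction time series that emulates low-rate (default
#' 40 Hz) video head tracking of a freely behaving mouse: angular velocity
#' follows a stationary Ornstein-Uhlenbeck (OU) process, giving epochs of
#' quiescence interleaved with fast turns, and the resulting head angle is
#' linearly interpolated onto a fine simulation grid exactly as a raw
#' tracking table would be.
#'
#' The OU velocity is advanced on the raw tracking grid with the exact
#' discrete update \eqn{\omega_{k+1} = a\omega_k + \sigma\sqrt{1-a^2} z_k},
#' \eqn{a = e^{-\Delta/\tau_\omega}}, so its stationary standard deviation
#' is `sigma_omega` regardless of the tracking rate.
#'
#' @param duration total duration in ms.
#' @param dt fine-grid sampling step in ms (default 1).
#' @param tau_omega relaxation time of angular velocity in ms.
#' @param sigma_omega stationary SD of angular velocity in rad/s.
#' @param raw_rate emulated tracking rate in Hz (default 40).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return An `hd_trajectory`: list with `t` (ms), `theta` (radians,
#'   unwrapped), `dt` (ms) and `meta = "synthetic"`.
#' @examples
#' traj <- ou_trajectory(10e3, dt = 1, seed = 1)
#' av <- angular_velocity(traj)
#' sd(av$omega)
#' @export
ou_trajectory <- function(duration, dt = 1, tau_omega = 200,
                          sigma_omega = 2, raw_rate = 40, seed = NULL) {
  stopifnot_scalar_pos(dt, "dt")
  stopifnot_scalar_pos(duration, "duration")
  stopifnot_scalar_pos(tau_omega, "tau_omega")
  stopifnot_scalar_pos(raw_rate, "raw_rate")
  if (!is.numeric(sigma_omega) || sigma_omega < 0) {
    stop("`sigma_omega` must be >= 0", call. = FALSE)
  }
  if (duration < 10 * dt) {
    stop("`duration` must be at least 10 * dt", call. = FALSE)
  }
  d_raw <- 1000 / raw_rate
  n_raw <- max(2L, ceiling(duration / d_raw) + 1L)
  t_raw <- (seq_len(n_raw) - 1L) * d_raw
  a <- exp(-d_raw / tau_omega)
  omega <- with_seed(seed, {
    z <- stats::rnorm(n_raw)
    w <- numeric(n_raw)
    w[1L] <- sigma_omega * z[1L]
    s <- sigma_omega * sqrt(1 - a^2)
    for (k in 2:n_raw) w[k] <- a * w[k - 1L] + s * z[k]
    w
  })
  # integrate velocity (rad/s) on the raw grid with the left-endpoint
  # rule: each raw interval's slope is exactly one OU sample, so the
  # centered-difference derivative of the interpolated angle recovers the
  # velocity process without attenuation
  theta_raw <- c(0, cumsum(omega[-n_raw] * d_raw / 1000))
  t_fine <- seq(0, t_raw[n_raw], by = dt)
  theta <- stats::approx(t_raw, theta_raw, xout = t_fine)$y
  new_trajectory(t_fine, theta, dt, "synthetic")
}

#' Load a head-tracking table onto a uniform fine grid
#'
#' Accepts either a data frame or a path to a delimited text file with
#' columns `time_s` and `angle_rad` (or `angle_deg` with `degrees = TRUE`).
#' Angles are unwrapped before interpolation so the path never crosses the
#' 0/2*pi seam the wrong way, then linearly interpolated onto a uniform
#' grid of step `dt` ms.
#'
#' @param x data frame or file path.
#' @param dt target sampling step in ms.
#' @param degrees if `TRUE`, the angle column is in degrees (column
#'   `angle_deg` is also accepted).
#' @return An `hd_trajectory` with `meta = "loaded"`.
#' @export
load_tracking <- function(x, dt = 1, degrees = FALSE) {
  stopifnot_scalar_pos(dt, "dt")
  if (is.character(x)) x <- utils::read.csv(x)
  if (!is.data.frame(x)) stop("`x` must be a data frame or file path",
                              call. = FALSE)
  tcol <- intersect(c("time_s", "time"), names(x))[1L]
  acol <- intersect(c("angle_rad", "angle_deg", "angle"), names(x))[1L]
  if (is.na(tcol) || is.na(acol)) {
    stop("tracking table needs columns `time_s` and `angle_rad`/`angle_deg`",
         call. = FALSE)
  }
  if (identical(acol, "angle_deg")) degrees <- TRUE
  tms <- as.numeric(x[[tcol]]) * 1000
  ang <- as.numeric(x[[acol]])
  if (degrees) ang <- ang * pi / 180
  if (length(tms) < 2L) stop("need at least 2 tracking samples", call. = FALSE)
  if (any(diff(tms) <= 0)) stop("tracking times must be strictly increasing",
                                call. = FALSE)
  ang <- unwrap_angle(ang)
  t_fine <- seq(tms[1L], tms[length(tms)], by = dt)
  theta <- stats::approx(tms, ang, xout = t_fine)$y
  new_trajectory(t_fine, theta, dt, "loaded")
}

#' Angular head velocity by centered differences
#'
#' Interior samples use the centered approximation
#' \eqn{\dot\theta(t_i) \approx (\theta_{i+1}-\theta_{i-1})/(t_{i+1}-t_{i-1})}
#' on the unwrapped angle; the two boundary samples use one-sided
#' differences so the series keeps the full trajectory length.
#'
#' @param traj an `hd_trajectory` of length >= 3.
#' @return List with `t` (ms), `omega` (signed angular velocity, rad/s;
#'   positive = counterclockwise) and `speed = abs(omega)`.
#' @export
angular_velocity <- function(traj) {
  stopifnot(inherits(traj, "hd_trajectory"))
  th <- traj$theta
  n <- length(th)
  if (n < 3L) stop("trajectory must have at least 3 samples", call. = FALSE)
  dt_s <- traj$dt / 1000
  omega <- numeric(n)
  omega[2:(n - 1L)] <- (th[3:n] - th[1:(n - 2L)]) / (2 * dt_s)
  omega[1L] <- (th[2L] - th[1L]) / dt_s
  omega[n] <- (th[n] - th[n - 1L]) / dt_s
  list(t = traj$t, omega = omega, speed = abs(omega))
}

#' Anticipatory (effective) trajectory
#'
#' An HD cell with anticipatory time interval (ATI) `A` effectively
#' experiences the trajectory \eqn{\theta_A(t) = \theta_T(t) + A\,\dot\theta_T(t)},
#' i.e. its preferred angle shifts from \eqn{\theta} to \eqn{\theta - \omega A}
#' during a turn at angular velocity \eqn{\omega}.
#'
#' @param traj an `hd_trajectory`.
#' @param ati anticipatory time interval in ms (negative values are
#'   accepted but nonphysiological).
#' @return An `hd_trajectory` on the same grid.
#' @export
effective_trajectory <- function(traj, ati) {
  stopifnot(inherits(traj, "hd_trajectory"))
  if (!is.numeric(ati) || length(ati) != 1L || !is.finite(ati)) {
    stop("`ati` must be a single finite number (ms)", call. = FALSE)
  }
  if (ati == 0) return(traj)
  om <- angular_velocity(traj)$omega
  new_trajectory(traj$t, traj$theta + (ati / 1000) * om, traj$dt, traj$meta)
}
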