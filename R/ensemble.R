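# The presynaptic head-direction (HD) population: tuning curves,
# Beta-distributed cell parameters, preferred-angle (PA) distributions,
# anticipatory rate modulation and Poisson spike generation.

#' Gaussian (von-Mises-like) HD tuning curve
#'
#' \deqn{f(\theta) = (f_{max} - f_{bg})\, e^{\epsilon(\cos\theta - 1)} + f_{bg}}
#'
#' The curve is 2*pi-periodic with its maximum `f_max` at zero offset and a
#' floor near the background rate `f_bg`; `epsilon` concentrates the tuning
#' (larger = narrower).
#'
#' @param theta_offset angular offset(s) from the preferred angle, radians.
#' @param f_bg background firing rate, Hz.
#' @param f_max maximum firing rate, Hz (>= `f_bg`).
#' @param epsilon tuning concentration, dimensionless (>= 0).
#' @return Firing rate(s) in Hz, same length as `theta_offset`.
#' @examples
#' tuning_curve(pi, f_bg = 1, f_max = 40, epsilon = 4) # ~ 1.013 Hz
#' @export
tuning_curve <- function(theta_offset, f_bg, f_max, epsilon) {
  (f_max - f_bg) * exp(epsilon * (cos(theta_offset) - 1)) + f_bg
}

#' Specification of a shifted/scaled Beta distribution
#'
#' Cell parameters are drawn from Beta(`a`, `b`) stretched to the interval
#' `[loc, loc + scale]`.
#'
#' @param a,b positive shape parameters.
#' @param loc location offset (units of the target parameter).
#' @param scale range (same units, > 0).
#' @return A `beta_spec` object.
#' @export
beta_spec <- function(a, b, loc = 0, scale = 1) {
  stopifnot_scalar_pos(a, "a"); stopifnot_scalar_pos(b, "b")
  stopifnot_scalar_pos(scale, "scale")
  if (!is.numeric(loc) || length(loc) != 1L || !is.finite(loc)) {
    stop("`loc` must be a single finite number", call. = FALSE)
  }
  structure(list(a = a, b = b, loc = loc, scale = scale),
            class = "beta_spec")
}

#' Draw from a shifted/scaled Beta distribution
#' @param spec a [beta_spec()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` values in `[loc, loc + scale]`.
#' @export
sample_beta <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "beta_spec")) stop("`spec` must be a beta_spec",
                                         call. = FALSE)
  with_seed(seed, spec$loc + spec$scale * stats::rbeta(n, spec$a, spec$b))
}

#' HD ensemble specification
#'
#' Describes a heterogeneous presynaptic HD population. Per-cell background
#' rate, maximum rate, tuning concentration and anticipatory time interval
#' (ATI) are drawn independently from shifted Beta distributions; preferred
#' angles are drawn uniformly or from a random periodic (Brownian-bridge)
#' density. The default Beta shapes are provisional stand-ins tuned to the
#' reported anterodorsal-thalamus HD statistics: mean background rate
#' ~3.3 Hz, mean peak rate 60 Hz, broad tuning (mean epsilon ~3.7, half
#' width at half max roughly 35 degrees), and mean ATI 50 ms.
#'
#' @param n_cells population size.
#' @param beta_fbg,beta_fmax,beta_epsilon,beta_ati [beta_spec()]s for the
#'   four per-cell parameters.
#' @param pa_mode `"uniform"` or `"bridge"` preferred-angle distribution.
#' @param bridge_roughness bridge log-density SD scale (`"bridge"` mode).
#' @param ati_fixed if non-`NULL`, every cell gets this ATI (ms) instead of
#'   a Beta draw (used for fixed-ATI sweeps).
#' @param seed integer seed for [sample_ensemble()].
#' @return An `ensemble_spec` object.
#' @export
ensemble_spec <- function(n_cells = 1000,
                          beta_fbg = beta_spec(2, 4, 0, 10),
                          beta_fmax = beta_spec(3, 3, 20, 80),
                          beta_epsilon = beta_spec(2, 4, 1, 8),
                          beta_ati = beta_spec(2, 2, 0, 100),
                          pa_mode = c("uniform", "bridge"),
                          bridge_roughness = 1,
                          ati_fixed = NULL,
                          seed = 1L) {
  pa_mode <- match.arg(pa_mode)
  if (!is.numeric(n_cells) || n_cells < 1) stop("`n_cells` must be >= 1",
                                                call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), beta_fbg = beta_fbg,
                 beta_fmax = beta_fmax, beta_epsilon = beta_epsilon,
                 beta_ati = beta_ati, pa_mode = pa_mode,
                 bridge_roughness = bridge_roughness,
                 ati_fixed = ati_fixed, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Sample an HD cell population
#'
#' Draws `n_cells` parameter sets from the spec's Beta distributions.
#' Because independent draws of `f_bg` and `f_max` could invert their
#' order, any pair with `f_max < f_bg` is redrawn jointly until valid so
#' the tuning formula keeps its interpretation.
#'
#' @param spec an [ensemble_spec()].
#' @return A data frame (class `hd_ensemble`) with one row per cell and
#'   columns `f_bg`, `f_max`, `epsilon`, `ati`, `pa`; the PA density used
#'   (in `"bridge"` mode) is attached as attribute `pa_density`.
#' @export
sample_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- spec$n_cells
  with_seed(spec$seed, {
    f_bg <- sample_beta(spec$beta_fbg, n)
    f_max <- sample_beta(spec$beta_fmax, n)
    bad <- which(f_max < f_bg)
    while (length(bad)) {
      f_bg[bad] <- sample_beta(spec$beta_fbg, length(bad))
      f_max[bad] <- sample_beta(spec$beta_fmax, length(bad))
      bad <- bad[f_max[bad] < f_bg[bad]]
    }
    epsilon <- sample_beta(spec$beta_epsilon, n)
    ati <- if (is.null(spec$ati_fixed)) sample_beta(spec$beta_ati, n)
           else rep(as.numeric(spec$ati_fixed), n)
    pa <- sample_pa(n, mode = spec$pa_mode,
                    roughness = spec$bridge_roughness)
    ens <- data.frame(f_bg = f_bg, f_max = f_max, epsilon = epsilon,
                      ati = ati, pa = pa$pa)
    class(ens) <- c("hd_ensemble", "data.frame")
    attr(ens, "pa_density") <- pa$density
    attr(ens, "spec") <- spec
    ens
  })
}

#' Firing-rate time series of one HD cell along a trajectory
#'
#' The cell's rate is its tuning curve evaluated at the offset between its
#' preferred angle and the *effective* (anticipatory) trajectory:
#' \eqn{r(t) = f(\mathrm{pa} - \theta_A(t))} with
#' \eqn{\theta_A(t) = \theta_T(t) + A\dot\theta_T(t)}.
#'
#' @param cell a single-row data frame or list with `f_bg`, `f_max`,
#'   `epsilon`, `ati` (ms), `pa` (radians).
#' @param traj an `hd_trajectory`.
#' @param omega optional precomputed angular velocity (rad/s) on the
#'   trajectory grid, to avoid recomputation across cells.
#' @return Numeric rate series in Hz on the trajectory grid.
#' @export
cell_rate_series <- function(cell, traj, omega = NULL) {
  stopifnot(inherits(traj, "hd_trajectory"))
  if (is.null(omega)) omega <- angular_velocity(traj)$omega
  theta_eff <- traj$theta + (cell$ati / 1000) * omega
  tuning_curve(cell$pa - theta_eff, cell$f_bg, cell$f_max, cell$epsilon)
}

#' Inhomogeneous Poisson spike train with absolute dead time
#'
#' Samples spikes by thinning: homogeneous candidates at the maximum rate
#' are accepted with probability `r(t)/r_max`, then any candidate within
#' `refractory` ms of the last accepted spike is discarded, which is
#' equivalent to silencing the intensity for `refractory` ms after each
#' spike.
#'
#' @param rate nonnegative rate series in Hz on a uniform grid of step `dt`.
#' @param dt grid step in ms.
#' @param refractory absolute dead time in ms (default 4).
#' @param seed optional integer seed.
#' @return Sorted spike times in ms (class `spike_train`); every
#'   inter-spike interval is >= `refractory`.
#' @export
generate_spike_train <- function(rate, dt, refractory = 4, seed = NULL) {
  if (any(rate < 0)) stop("`rate` must be nonnegative", call. = FALSE)
  stopifnot_scalar_pos(dt, "dt")
  if (refractory < 0) stop("`refractory` must be >= 0", call. = FALSE)
  n <- length(rate)
  t_end <- (n - 1L) * dt
  rmax <- max(rate)
  if (rmax == 0 || t_end <= 0) {
    return(structure(numeric(0), class = "spike_train",
                     refractory = refractory))
  }
  times <- with_seed(seed, {
    m <- stats::rpois(1L, rmax * t_end / 1000)
    tc <- sort(stats::runif(m, 0, t_end))
    u <- stats::runif(m)
    r_at <- stats::approx(seq(0, t_end, by = dt), rate, xout = tc)$y
    tc[u < r_at / rmax]
  })
  if (refractory > 0 && length(times) > 1L) {
    keep <- logical(length(times))
    last <- -Inf
    for (j in seq_along(times)) {
      if (times[j] - last >= refractory) {
        keep[j] <- TRUE
        last <- times[j]
      }
    }
    times <- times[keep]
  }
  structure(times, class = "spike_train", refractory = refractory)
}

#' Sample preferred angles, optionally from a random periodic density
#'
#' In `"uniform"` mode PAs are i.i.d. uniform on `[0, 2*pi)`. In
#' `"bridge"` mode a random 2*pi-periodic probability density is built
#' from a standard Brownian bridge `B` on `[0, 2*pi]` (pinned at both
#' ends to guarantee periodicity): the density is proportional to
#' `exp(roughness * B)` — the bridge acts as a random log-density, which
#' keeps the density positive — normalized to unit circular integral.
#' Samples are then drawn by inverse-transform sampling of its CDF.
#'
#' @param n number of preferred angles to draw.
#' @param mode `"uniform"` or `"bridge"`.
#' @param roughness bridge amplitude (log-density SD scale); 0 degenerates
#'   to the uniform density.
#' @param seed optional integer seed.
#' @param grid_n resolution of the density grid.
#' @return List with `pa` (n angles in `[0, 2*pi)`) and `density`
#'   (a `pa_density`: `grid`, `density`, periodic, unit integral).
#' @export
sample_pa <- function(n, mode = c("uniform", "bridge"), roughness = 1,
                      seed = NULL, grid_n = 1024L) {
  mode <- match.arg(mode)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (roughness < 0) stop("`roughness` must be >= 0", call. = FALSE)
  with_seed(seed, {
    grid <- seq(0, 2 * pi, length.out = grid_n + 1L)
    if (mode == "uniform" || roughness == 0) {
      dens <- rep(1 / (2 * pi), grid_n + 1L)
      pa <- stats::runif(n, 0, 2 * pi)
    } else {
      dw <- stats::rnorm(grid_n) * sqrt(diff(grid))
      w <- c(0, cumsum(dw))
      bridge <- w - grid / (2 * pi) * w[grid_n + 1L]
      logd <- roughness * bridge
      dens <- exp(logd - max(logd))
      dens <- dens / trapz(grid, dens)
      cdf <- c(0, cumsum((dens[-1L] + dens[-(grid_n + 1L)]) / 2 *
                           diff(grid)))
      cdf <- cdf / cdf[grid_n + 1L]
      u <- stats::runif(n)
      pa <- stats::approx(cdf, grid, xout = u, ties = "ordered")$y
    }
    list(pa = wrap_angle(pa),
         density = structure(list(grid = grid, density = dens),
                             class = "pa_density"))
  })
}

#' Circular 1-Wasserstein distance from the uniform distribution
#'
#' The heterogeneity score of a preferred-angle density: the optimal
#' transport cost (arc-length ground metric) between the density and the
#' uniform circular distribution,
#' \deqn{WD = \min_c \int_0^{2\pi} | F(\theta) - \theta/2\pi - c |\, d\theta,}
#' where the minimizing constant is the (length-weighted) median of the
#' CDF difference. Zero iff uniform; a point mass attains pi/2.
#'
#' @param density a `pa_density` (from [sample_pa()]) or a list with
#'   `grid` and `density` covering `[0, 2*pi]`, normalized to integral 1.
#' @return Nonnegative distance in radians.
#' @export
wasserstein_to_uniform <- function(density) {
  g <- density$grid
  d <- density$density
  if (any(d < 0)) stop("density must be nonnegative", call. = FALSE)
  total <- trapz(g, d)
  if (abs(total - 1) > 1e-6) {
    stop("density must integrate to 1 over the circle", call. = FALSE)
  }
  m <- length(g)
  cdf <- c(0, cumsum((d[-1L] + d[-m]) / 2 * diff(g)))
  h <- cdf - g / (2 * pi)
  # uniform grid assumed for the weighted median; enforced by construction
  c_star <- stats::median(h)
  trapz(g, abs(h - c_star))
}
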