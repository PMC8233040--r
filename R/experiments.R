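# Orchestration of the three in-silico experiments: speed coding with
# depressing vs non-depressing synapses, the fixed-ATI sweep, and the
# population direction/speed tradeoff.

#' Simulate the summed synaptic drive of an HD ensemble onto one LR cell
#'
#' The workhorse shared by all experiments. For each HD cell it computes
#' the anticipatory rate series, draws an inhomogeneous Poisson spike
#' train (4 ms dead time) from a per-cell RNG stream, propagates the
#' spikes through the Tsodyks-Markram synapse (event-driven, exact), and
#' accumulates the conductance jumps of all synapses on the simulation
#' grid; the total conductance is then the jump train filtered by the
#' `tau_g` exponential decay. Both synapse modes reuse the *same* spike
#' trains, so the depressing / non-depressing contrast isolates the
#' synaptic dynamics. Non-depressing jumps are `weight * U`, matching the
#' first-pulse (rested) amplitude of the depressing synapse.
#'
#' @param traj an `hd_trajectory`.
#' @param ensemble an `hd_ensemble` from [sample_ensemble()].
#' @param tm a [tm_params()].
#' @param modes character subset of `c("depressing", "non_depressing")`.
#' @param refractory spike dead time, ms.
#' @param awc_threshold if non-`NULL`, also compute each cell's
#'   active-window (> threshold Hz) rate-speed correlation on the fly.
#' @param seed master seed; spawns one stream per cell, so results are
#'   independent of cell order.
#' @return List with `t`, per-mode total conductance (`g_depressing`,
#'   `g_non_depressing`), `awc` (per-cell correlations or `NULL`), and
#'   `spike_counts`.
#' @export
simulate_ensemble_drive <- function(traj, ensemble, tm = tm_params(),
                                    modes = c("depressing",
                                              "non_depressing"),
                                    refractory = 4, awc_threshold = NULL,
                                    seed = 1L) {
  stopifnot(inherits(traj, "hd_trajectory"))
  modes <- match.arg(modes, several.ok = TRUE)
  av <- angular_velocity(traj)
  omega <- av$omega
  speed <- av$speed
  theta <- traj$theta
  dt <- traj$dt
  n <- length(theta)
  nc <- nrow(ensemble)
  jumps_dep <- if ("depressing" %in% modes) numeric(n)
  jumps_nd <- if ("non_depressing" %in% modes) numeric(n)
  awc <- if (!is.null(awc_threshold)) rep(NA_real_, nc)
  counts <- integer(nc)
  seeds <- derive_seeds(seed, nc)
  for (i in seq_len(nc)) {
    cell <- ensemble[i, ]
    r <- tuning_curve(cell$pa - (theta + cell$ati / 1000 * omega),
                      cell$f_bg, cell$f_max, cell$epsilon)
    st <- generate_spike_train(r, dt, refractory = refractory,
                               seed = seeds[i])
    counts[i] <- length(st)
    if (!is.null(awc_threshold)) {
      act <- r > awc_threshold
      if (sum(act) >= 100L && stats::sd(r[act]) > 0 &&
          stats::sd(speed[act]) > 0) {
        awc[i] <- stats::cor(r[act], speed[act])
      }
    }
    if (length(st)) {
      idx <- pmin(n, floor(as.numeric(st) / dt) + 1L)
      if (!is.null(jumps_dep)) {
        rel <- tm_releases(as.numeric(st), tm)
        agg <- rowsum(tm$weight * rel, idx)
        ii <- as.integer(rownames(agg))
        jumps_dep[ii] <- jumps_dep[ii] + agg[, 1L]
      }
      if (!is.null(jumps_nd)) {
        agg <- rowsum(rep(tm$weight * tm$U, length(idx)), idx)
        ii <- as.integer(rownames(agg))
        jumps_nd[ii] <- jumps_nd[ii] + agg[, 1L]
      }
    }
  }
  out <- list(t = traj$t, spike_counts = counts)
  if (!is.null(jumps_dep)) {
    out$g_depressing <- decay_filter(jumps_dep, dt, tm$tau_g)
  }
  if (!is.null(jumps_nd)) {
    out$g_non_depressing <- decay_filter(jumps_nd, dt, tm$tau_g)
  }
  out$awc <- awc
  out
}

#' Speed-coding experiment: depressing vs non-depressing synapses
#'
#' Runs one trajectory through one HD ensemble under both synapse modes
#' and quantifies how the postsynaptic rate encodes angular head speed:
#' lag-resolved correlation and mutual information, optimal lags, speed
#' and signed-velocity tuning curves, and the distribution of presynaptic
#' active-window rate-speed correlations.
#'
#' @param n_cells HD population size (default 1000, a desk-scale stand-in
#'   for the full 7500-cell ensemble).
#' @param duration_s trajectory duration in seconds.
#' @param dt simulation step, ms.
#' @param spec an [ensemble_spec()]; `n_cells` above overrides its size.
#' @param tm a [tm_params()].
#' @param tau_m readout integration time constant, ms.
#' @param lags lag grid, ms.
#' @param bins MI bins.
#' @param kernel_sd Gaussian SD (ms) used to smooth the readout rate
#'   before analysis, matching the spike-rate estimator's resolution;
#'   `NULL` disables smoothing.
#' @param awc_threshold active-window threshold, Hz.
#' @param traj optional pre-built trajectory (otherwise an OU trajectory
#'   is generated from the seed).
#' @param tau_omega,sigma_omega OU trajectory parameters (ms, rad/s).
#' @param seed master seed.
#' @return List (class `speed_coding_result`) with per-mode readout rates,
#'   `corr` / `mi` lag-similarity objects, `speed_tuning`, `ahv_tuning`
#'   (signed), `awc`, the trajectory and resolved settings.
#' @export
run_speed_coding <- function(n_cells = 1000, duration_s = 120, dt = 1,
                             spec = NULL, tm = tm_params(), tau_m = 10,
                             lags = seq(-70, 70, by = 2), bins = 40L,
                             kernel_sd = 50, awc_threshold = 10, traj = NULL,
                             tau_omega = 200, sigma_omega = 2, seed = 1L) {
  seeds <- derive_seeds(seed, 3L)
  if (is.null(traj)) {
    traj <- ou_trajectory(duration_s * 1000, dt = dt,
                          tau_omega = tau_omega,
                          sigma_omega = sigma_omega, seed = seeds[1L])
  }
  if (is.null(spec)) spec <- ensemble_spec(n_cells = n_cells,
                                           seed = seeds[2L])
  spec$n_cells <- as.integer(n_cells)
  ens <- sample_ensemble(spec)
  av <- angular_velocity(traj)
  drive <- simulate_ensemble_drive(traj, ens, tm = tm,
                                   awc_threshold = awc_threshold,
                                   seed = seeds[3L])
  modes <- list()
  for (mode in c("depressing", "non_depressing")) {
    g <- drive[[paste0("g_", mode)]]
    rate <- rate_readout(g, dt, tau_m = tau_m)
    if (!is.null(kernel_sd)) rate <- gaussian_smooth(rate, kernel_sd, dt)
    corr <- lagged_correlation(rate, av$speed, dt, lags = lags)
    mi <- lagged_mutual_information(rate, av$speed, dt, lags = lags,
                                    bins = bins)
    modes[[mode]] <- list(
      rate = rate, corr = corr, mi = mi,
      max_corr = corr$max_value, corr_lag = corr$optimal_lag,
      max_mi = mi$max_value, mi_lag = mi$optimal_lag,
      speed_tuning = speed_tuning_curve(rate, av$speed),
      ahv_tuning = speed_tuning_curve(rate, av$omega))
  }
  structure(list(trajectory = traj, speed = av$speed, omega = av$omega,
                 depressing = modes$depressing,
                 non_depressing = modes$non_depressing,
                 awc = list(values = drive$awc,
                            mean = mean(drive$awc, na.rm = TRUE)),
                 ensemble = ens,
                 settings = list(n_cells = n_cells, dt = dt, tau_m = tau_m,
                                 kernel_sd = kernel_sd, lags = lags,
                                 bins = bins, tm = tm, seed = seed)),
            class = "speed_coding_result")
}

#' @export
print.speed_coding_result <- function(x, ...) {
  cat(sprintf(
    paste0("<speed_coding_result> %d HD cells, %.0f s\n",
           "  depressing:     max corr %.3f at lag %g ms; max MI %.3f bits at %g ms\n",
           "  non-depressing: max corr %.3f at lag %g ms\n"),
    x$settings$n_cells,
    (length(x$speed) - 1) * x$settings$dt / 1000,
    x$depressing$max_corr, x$depressing$corr_lag,
    x$depressing$max_mi, x$depressing$mi_lag,
    x$non_depressing$max_corr, x$non_depressing$corr_lag))
  invisible(x)
}

#' Fixed-ATI sweep (paired design)
#'
#' Repeats the depressing-mode speed-coding run with every HD cell's ATI
#' clamped to each value in `ati_values`. The trajectory, the per-cell
#' tuning parameter draws and the per-cell spike RNG streams are shared
#' across arms, so only the ATI (and the spike realizations it induces)
#' differs.
#'
#' @param ati_values fixed ATI values, ms (>= 0).
#' @inheritParams run_speed_coding
#' @return Data frame with one row per ATI: `ati_ms`, `optimal_lag_ms`,
#'   `max_corr`, `max_mi`, `mi_lag_ms`.
#' @export
run_ati_sweep <- function(ati_values = c(0, 25, 50, 75), n_cells = 1000,
                          duration_s = 120, dt = 1, spec = NULL,
                          tm = tm_params(), tau_m = 10,
                          lags = seq(-70, 70, by = 2), bins = 40L,
                          kernel_sd = 50, tau_omega = 200, sigma_omega = 2,
                          seed = 1L) {
  if (!length(ati_values) || any(ati_values < 0)) {
    stop("`ati_values` must be nonempty and >= 0", call. = FALSE)
  }
  seeds <- derive_seeds(seed, 3L)
  traj <- ou_trajectory(duration_s * 1000, dt = dt, tau_omega = tau_omega,
                        sigma_omega = sigma_omega, seed = seeds[1L])
  av <- angular_velocity(traj)
  if (is.null(spec)) spec <- ensemble_spec(n_cells = n_cells,
                                           seed = seeds[2L])
  spec$n_cells <- as.integer(n_cells)
  out <- lapply(ati_values, function(a) {
    spec_a <- spec
    spec_a$ati_fixed <- a
    ens <- sample_ensemble(spec_a)
    drive <- simulate_ensemble_drive(traj, ens, tm = tm,
                                     modes = "depressing",
                                     seed = seeds[3L])
    rate <- rate_readout(drive$g_depressing, dt, tau_m = tau_m)
    if (!is.null(kernel_sd)) rate <- gaussian_smooth(rate, kernel_sd, dt)
    corr <- lagged_correlation(rate, av$speed, dt, lags = lags)
    mi <- lagged_mutual_information(rate, av$speed, dt, lags = lags,
                                    bins = bins)
    data.frame(ati_ms = a, optimal_lag_ms = corr$optimal_lag,
               max_corr = corr$max_value, max_mi = mi$max_value,
               mi_lag_ms = mi$optimal_lag)
  })
  do.call(rbind, out)
}

#' Population tradeoff between direction and speed coding
#'
#' Simulates a population of LR cells, each receiving HD input whose
#' preferred angles are drawn from an independent random periodic
#' (Brownian-bridge) density with its own roughness. For each LR cell it
#' reports the Wasserstein heterogeneity of its PA density and four
#' coding scores (max lagged speed correlation and MI; circular-linear
#' direction correlation and direction MI at lag 0).
#'
#' @param n_lr number of simulated LR cells.
#' @param n_cells HD inputs per LR cell.
#' @param duration_s shared trajectory duration, seconds.
#' @param roughness_range range of the uniform per-cell bridge roughness
#'   draw; the default spans Wasserstein heterogeneities of ~0-0.5 rad.
#' @inheritParams run_speed_coding
#' @return Data frame (class `population_result`), one row per LR cell:
#'   `lr_id`, `roughness`, `wd`, `corr_speed`, `mi_speed`, `corr_dir`,
#'   `mi_dir`, `optimal_lag_ms`.
#' @export
run_population_tradeoff <- function(n_lr = 50, n_cells = 400,
                                    duration_s = 60, dt = 1,
                                    roughness_range = c(0, 1.2),
                                    tm = tm_params(), tau_m = 10,
                                    lags = seq(-70, 70, by = 2),
                                    bins = 40L, kernel_sd = 50,
                                    tau_omega = 200, sigma_omega = 2,
                                    seed = 1L) {
  if (n_lr < 2) stop("`n_lr` must be >= 2", call. = FALSE)
  seeds <- derive_seeds(seed, n_lr + 1L)
  traj <- ou_trajectory(duration_s * 1000, dt = dt, tau_omega = tau_omega,
                        sigma_omega = sigma_omega, seed = seeds[1L])
  av <- angular_velocity(traj)
  theta_w <- wrap_angle(traj$theta)
  rows <- lapply(seq_len(n_lr), function(j) {
    sj <- seeds[j + 1L]
    rough <- with_seed(sj, stats::runif(1, roughness_range[1L],
                                        roughness_range[2L]))
    spec <- ensemble_spec(n_cells = n_cells, pa_mode = "bridge",
                          bridge_roughness = rough, seed = sj)
    ens <- sample_ensemble(spec)
    wd <- wasserstein_to_uniform(attr(ens, "pa_density"))
    drive <- simulate_ensemble_drive(traj, ens, tm = tm,
                                     modes = "depressing", seed = sj)
    rate <- rate_readout(drive$g_depressing, dt, tau_m = tau_m)
    if (!is.null(kernel_sd)) rate <- gaussian_smooth(rate, kernel_sd, dt)
    corr <- lagged_correlation(rate, av$speed, dt, lags = lags)
    mi <- lagged_mutual_information(rate, av$speed, dt, lags = lags,
                                    bins = bins)
    dir_info <- direction_information(rate, theta_w, bins = bins)
    data.frame(lr_id = j, roughness = rough, wd = wd,
               corr_speed = corr$max_value, mi_speed = mi$max_value,
               corr_dir = dir_info$circ_lin_corr,
               mi_dir = dir_info$mi_bits,
               optimal_lag_ms = corr$optimal_lag)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("population_result", "data.frame")
  out
}

#' Rank-correlation permutation test for the population tradeoff
#'
#' Spearman rank correlation between two population scores with a
#' permutation p-value (two-sided).
#'
#' @param x,y numeric vectors (e.g. `wd` and `mi_dir`).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List with `rho` and `p_value`.
#' @export
rank_correlation_test <- function(x, y, n_perm = 2000L, seed = 1L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  rho <- stats::cor(x, y, method = "spearman")
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stats::cor(x, sample(y), method = "spearman")
    }, numeric(1))
  })
  p <- (1 + sum(abs(perms) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p_value = p)
}
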