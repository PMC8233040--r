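# Tsodyks-Markram (TM) short-term synaptic plasticity: event-driven exact
# dynamics, conductance traces, steady-state analytics, the non-depressing
# control synapse, and least-squares fitting to pulse-train amplitudes.
#
# Between spikes the state (x, u, g) relaxes linearly,
#   dx/dt = (1 - x)/tau_d,  du/dt = -u/tau_f,  dg/dt = -g/tau_g,
# and at each presynaptic spike
#   u+ = u- + U (1 - u-),  release = u+ x-,  x+ = x- (1 - u+),
#   g  jumps by weight * release.

#' TM synapse parameters
#'
#' @param tau_d depression (vesicle pool) recovery time, ms.
#' @param tau_f facilitation decay time, ms.
#' @param tau_g synaptic conductance decay time, ms. Not reported with the
#'   fitted set; the default of 10 ms is a package choice, exposed here.
#' @param U baseline release increment, in (0, 1].
#' @param weight synaptic weight (conductance units per unit release).
#' @return A `tm_params` object.
#' @examples
#' tm_params() # the fitted depressing thalamocortical synapse
#' @export
tm_params <- function(tau_d = 270, tau_f = 40, tau_g = 10, U = 0.28,
                      weight = 1) {
  stopifnot_scalar_pos(tau_d, "tau_d")
  stopifnot_scalar_pos(tau_f, "tau_f")
  stopifnot_scalar_pos(tau_g, "tau_g")
  stopifnot_scalar_pos(weight, "weight")
  if (!is.numeric(U) || length(U) != 1L || U <= 0 || U > 1) {
    stop("`U` must be in (0, 1]", call. = FALSE)
  }
  structure(list(tau_d = tau_d, tau_f = tau_f, tau_g = tau_g, U = U,
                 weight = weight), class = "tm_params")
}

#' @export
print.tm_params <- function(x, ...) {
  cat(sprintf(
    "<tm_params> tau_d = %g ms, tau_f = %g ms, tau_g = %g ms, U = %g, weight = %g\n",
    x$tau_d, x$tau_f, x$tau_g, x$U, x$weight))
  invisible(x)
}

#' TM synapse state
#' @param x vesicle-pool fraction in `[0, 1]`.
#' @param u release probability in `[0, 1]`.
#' @param g synaptic conductance (>= 0).
#' @param t_last time of last update, ms.
#' @return A `tm_state` object.
#' @export
tm_state <- function(x = 1, u = 0, g = 0, t_last = 0) {
  stopifnot(x >= 0, x <= 1, u >= 0, u <= 1, g >= 0)
  structure(list(x = x, u = u, g = g, t_last = t_last), class = "tm_state")
}

#' Relax a TM state over a spike-free interval (closed form)
#'
#' @param state a [tm_state()].
#' @param dt interval length, ms (>= 0).
#' @param params a [tm_params()].
#' @return The relaxed `tm_state`, `t_last` advanced by `dt`.
#' @export
tm_relax <- function(state, dt, params) {
  if (!is.numeric(dt) || dt < 0) stop("`dt` must be >= 0", call. = FALSE)
  tm_state(x = 1 - (1 - state$x) * exp(-dt / params$tau_d),
           u = state$u * exp(-dt / params$tau_f),
           g = state$g * exp(-dt / params$tau_g),
           t_last = state$t_last + dt)
}

#' Apply a presynaptic spike to a TM state
#'
#' @param state a [tm_state()] (pre-spike values).
#' @param params a [tm_params()].
#' @return List with `state` (post-spike) and `release` (`u+ x-`, the
#'   per-pulse amplitude proxy).
#' @export
tm_spike <- function(state, params) {
  u_plus <- state$u + params$U * (1 - state$u)
  release <- u_plus * state$x
  list(state = tm_state(x = state$x * (1 - u_plus), u = u_plus,
                        g = state$g + params$weight * release,
                        t_last = state$t_last),
       release = release)
}

# Per-spike releases for a sorted spike train, via the exact two-variable
# recursion; the workhorse of the ensemble simulation.
tm_releases <- function(times, params) {
  ns <- length(times)
  if (ns == 0L) return(numeric(0))
  U <- params$U
  ed <- exp(-diff(times) / params$tau_d)
  eu <- exp(-diff(times) / params$tau_f)
  rel <- numeric(ns)
  x <- 1; u <- 0
  for (k in seq_len(ns)) {
    up <- u + U * (1 - u)
    rel[k] <- up * x
    if (k < ns) {
      x <- 1 - (1 - x * (1 - up)) * ed[k]
      u <- up * eu[k]
    }
  }
  rel
}

#' Conductance trace of a TM synapse driven by a spike train
#'
#' Alternates exact relaxation and spike updates over the train and
#' evaluates the conductance analytically between events (no accumulated
#' integration error), sampled on a uniform grid.
#'
#' @param spikes sorted spike times in ms (a `spike_train` or numeric).
#' @param params a [tm_params()].
#' @param dt output grid step, ms.
#' @param duration total trace duration in ms (default: last spike +
#'   `5 * tau_g`).
#' @return List with `t`, `g` (conductance series), `releases` (per-spike)
#'   and `amplitudes` (releases normalized to the first, the standard
#'   pulse-train normalization).
#' @export
conductance_train <- function(spikes, params, dt = 1, duration = NULL) {
  times <- as.numeric(spikes)
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1L) {
    stop("`spikes` must be strictly increasing", call. = FALSE)
  }
  duration <- duration %||%
    (if (length(times)) max(times) + 5 * params$tau_g else 100)
  tg <- seq(0, duration, by = dt)
  g <- numeric(length(tg))
  rel <- tm_releases(times, params)
  g_last <- 0; t_last <- 0
  bounds <- c(times, Inf)
  start_idx <- 1L
  for (k in seq_along(bounds)) {
    in_seg <- tg[start_idx:length(tg)] < bounds[k]
    if (any(in_seg)) {
      seg <- start_idx:(start_idx + sum(in_seg) - 1L)
      g[seg] <- g_last * exp(-(tg[seg] - t_last) / params$tau_g)
      start_idx <- seg[length(seg)] + 1L
    }
    if (k <= length(times)) {
      g_last <- g_last * exp(-(times[k] - t_last) / params$tau_g) +
        params$weight * rel[k]
      t_last <- times[k]
    }
    if (start_idx > length(tg) && k > length(times)) break
  }
  amps <- if (length(rel)) rel / rel[1L] else numeric(0)
  list(t = tg, g = g, releases = rel, amplitudes = amps)
}

#' Steady state of a TM synapse under periodic stimulation
#'
#' Closed-form fixed point of the event-driven map under pulses at a fixed
#' rate: with \eqn{\Delta = 1000/\mathrm{rate}} ms,
#' \eqn{e_u = e^{-\Delta/\tau_f}}, \eqn{e_d = e^{-\Delta/\tau_d}},
#' \deqn{u^-_{ss} = \frac{U e_u}{1 - (1-U) e_u},\quad
#'       u^+_{ss} = u^-_{ss} + U(1 - u^-_{ss}),\quad
#'       x^-_{ss} = \frac{1 - e_d}{1 - e_d (1 - u^+_{ss})}.}
#'
#' @param rate stimulation rate, Hz (> 0).
#' @param params a [tm_params()].
#' @return List with `x_ss` (pre-spike pool), `u_ss` (post-spike release
#'   probability) and `release_ss = u_ss * x_ss`.
#' @export
tm_steady_state <- function(rate, params) {
  stopifnot_scalar_pos(rate, "rate")
  delta <- 1000 / rate
  eu <- exp(-delta / params$tau_f)
  ed <- exp(-delta / params$tau_d)
  U <- params$U
  u_minus <- U * eu / (1 - (1 - U) * eu)
  u_plus <- u_minus + U * (1 - u_minus)
  x_minus <- (1 - ed) / (1 - ed * (1 - u_plus))
  list(x_ss = x_minus, u_ss = u_plus, release_ss = u_plus * x_minus)
}

#' Non-depressing (static exponential) control synapse
#'
#' Every spike adds the same `weight` to the conductance, which decays with
#' `tau_g`; no history dependence of the jump size (instantaneous rise).
#'
#' @param spikes sorted spike times, ms.
#' @param weight jump size per spike (conductance units).
#' @param tau_g conductance decay time, ms.
#' @param dt output grid step, ms.
#' @param duration trace duration, ms (default: last spike + `5 * tau_g`).
#' @return List with `t` and `g`.
#' @export
exp_synapse <- function(spikes, weight, tau_g, dt = 1, duration = NULL) {
  times <- as.numeric(spikes)
  duration <- duration %||%
    (if (length(times)) max(times) + 5 * tau_g else 100)
  tg <- seq(0, duration, by = dt)
  g <- numeric(length(tg))
  if (length(times)) {
    for (ts in times) {
      after <- tg >= ts
      g[after] <- g[after] + weight * exp(-(tg[after] - ts) / tau_g)
    }
  }
  list(t = tg, g = g)
}

#' Fit TM parameters to a normalized pulse-amplitude train
#'
#' Exhaustive grid search over `(tau_d, tau_f, U)` minimizing the sum of
#' squared differences between the model's normalized per-pulse releases
#' (first pulse = 1) and the data, for a regular pulse train at interval
#' `isi`. Ties are broken by the lexicographically smallest
#' `(tau_d, tau_f, U)`. The synaptic weight is recovered separately from
#' the raw first amplitude when one is supplied.
#'
#' @param amps normalized amplitudes (first element 1) or raw amplitudes
#'   with `normalized = FALSE`.
#' @param isi inter-pulse interval in ms (e.g. 100 for a 10 Hz train).
#' @param grid list with numeric vectors `tau_d`, `tau_f`, `U` defining the
#'   search grid (defaults bracket physiological ranges: tau_d 10-1000 ms
#'   step 10, tau_f 5-500 ms step 5, U 0.02-0.98 step 0.02).
#' @param normalized whether `amps` are already normalized.
#' @return A [tm_params()] with the fitted `tau_d`, `tau_f`, `U` (and
#'   `weight` if raw amplitudes were given); attributes `loss` (minimum
#'   sum of squares) and `fitted` (model normalized amplitudes).
#' @examples
#' p <- tm_params(tau_d = 270, tau_f = 40, U = 0.28)
#' amps <- conductance_train(seq(0, 900, by = 100), p)$amplitudes
#' fit_tm(amps, isi = 100)
#' @export
fit_tm <- function(amps, isi = 100,
                   grid = list(tau_d = seq(10, 1000, by = 10),
                               tau_f = seq(5, 500, by = 5),
                               U = seq(0.02, 0.98, by = 0.02)),
                   normalized = TRUE) {
  amps <- as.numeric(amps)
  if (length(amps) < 2L) stop("need at least 2 pulse amplitudes",
                              call. = FALSE)
  if (!all(lengths(grid[c("tau_d", "tau_f", "U")]) >= 1L)) {
    stop("`grid` must contain nonempty tau_d, tau_f, U", call. = FALSE)
  }
  raw1 <- amps[1L]
  if (!normalized) amps <- amps / amps[1L]
  if (abs(amps[1L] - 1) > 1e-8) {
    stop("normalized amplitudes must start at 1", call. = FALSE)
  }
  combos <- expand.grid(U = grid$U, tau_f = grid$tau_f, tau_d = grid$tau_d,
                        KEEP.OUT.ATTRS = FALSE)
  ed <- exp(-isi / combos$tau_d)
  eu <- exp(-isi / combos$tau_f)
  U <- combos$U
  np <- length(amps)
  x <- rep(1, nrow(combos)); u <- numeric(nrow(combos))
  loss <- numeric(nrow(combos))
  for (k in seq_len(np)) {
    up <- u + U * (1 - u)
    rel <- up * x
    loss <- loss + (rel / U - amps[k])^2   # first release from rest is U
    x <- 1 - (1 - x * (1 - up)) * ed
    u <- up * eu
  }
  cand <- which(loss <= min(loss) + 1e-12)
  cand <- cand[order(combos$tau_d[cand], combos$tau_f[cand],
                     combos$U[cand])][1L]
  best <- combos[cand, ]
  weight <- if (normalized) 1 else raw1 / best$U
  fit <- tm_params(tau_d = best$tau_d, tau_f = best$tau_f, U = best$U,
                   weight = weight)
  attr(fit, "loss") <- loss[cand]
  attr(fit, "fitted") <- {
    rel <- tm_releases(seq(0, by = isi, length.out = np), fit)
    rel / rel[1L]
  }
  fit
}
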