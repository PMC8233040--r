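# Postsynaptic LR readouts: conductance summation, a first-order rate
# readout (reference implementation), a conductance-driven Hodgkin-Huxley
# point neuron, and firing-rate estimation from spikes.

#' Sum per-synapse conductance series
#'
#' Point summation of synaptic conductances onto the soma; valid because
#' synaptic placement does not qualitatively shape the readout here.
#'
#' @param g_list list of numeric conductance series on a shared time grid.
#' @return Elementwise sum.
#' @export
sum_conductances <- function(g_list) {
  if (!length(g_list)) stop("empty conductance list", call. = FALSE)
  n <- lengths(g_list)
  if (length(unique(n)) != 1L) {
    stop("all conductance series must share one time grid", call. = FALSE)
  }
  Reduce(`+`, g_list)
}

#' Rate-based postsynaptic readout
#'
#' First-order low-pass of the total synaptic conductance with membrane
#' time constant `tau_m`, followed by an affine map to firing rate and
#' optional rectification at zero. This is the reference readout: its
#' output is what the coding analysis treats as the LR firing rate, and
#' all correlation/MI scores are invariant to `gain` and `baseline`.
#'
#' @param total_g total conductance series on a uniform grid.
#' @param dt grid step, ms.
#' @param tau_m integration time constant, ms.
#' @param gain Hz per unit conductance.
#' @param baseline additive rate, Hz.
#' @param rectify clip negative rates to zero.
#' @return Firing-rate series in Hz.
#' @export
rate_readout <- function(total_g, dt, tau_m = 10, gain = 1, baseline = 0,
                         rectify = TRUE) {
  stopifnot_scalar_pos(tau_m, "tau_m")
  stopifnot_scalar_pos(gain, "gain")
  if (baseline < 0) stop("`baseline` must be >= 0", call. = FALSE)
  a <- exp(-dt / tau_m)
  y <- as.numeric(stats::filter((1 - a) * total_g, a, method = "recursive",
                                init = total_g[1L]))
  r <- baseline + gain * y
  if (rectify) r[r < 0] <- 0
  r
}

#' Hodgkin-Huxley point-neuron parameters
#'
#' Single-compartment conductances: fast sodium, delayed-rectifier
#' potassium, and a slow non-inactivating potassium current standing in
#' for the Kv1.1-mediated component that delays LR spiking. Kinetics are
#' standard cortical point-neuron forms; all values are configuration.
#'
#' @param c_m membrane capacitance, uF/cm^2.
#' @param g_na,g_kdr,g_ks,g_leak maximal conductances, mS/cm^2.
#' @param e_na,e_k,e_leak,e_syn reversal potentials, mV.
#' @param tau_ks slow-potassium activation time constant, ms.
#' @return A `hh_params` object.
#' @export
hh_params <- function(c_m = 1, g_na = 120, g_kdr = 36, g_ks = 0.5,
                      g_leak = 0.3, e_na = 50, e_k = -77, e_leak = -54.4,
                      e_syn = 0, tau_ks = 50) {
  structure(list(c_m = c_m, g_na = g_na, g_kdr = g_kdr, g_ks = g_ks,
                 g_leak = g_leak, e_na = e_na, e_k = e_k, e_leak = e_leak,
                 e_syn = e_syn, tau_ks = tau_ks), class = "hh_params")
}

#' Conductance-driven Hodgkin-Huxley point neuron
#'
#' Integrates a single-compartment HH system with synaptic current
#' `g_syn(t) * (e_syn - V)` using exponential-Euler gating updates at an
#' internal step of `dt_int` ms (the input series is linearly resampled).
#' Spikes are detected as upward crossings of -20 mV with a -40 mV reset
#' hysteresis so a single action potential is never double-counted.
#'
#' @param total_g total synaptic conductance series (mS/cm^2) on a grid of
#'   step `dt` ms.
#' @param dt input grid step, ms.
#' @param params an [hh_params()].
#' @param dt_int internal integration step, ms (<= 0.05 recommended).
#' @return List with `spikes` (spike times, ms, class `spike_train`),
#'   `t` and `v` (membrane potential on the internal grid).
#' @export
hh_point_neuron <- function(total_g, dt, params = hh_params(),
                            dt_int = 0.025) {
  if (dt_int > 0.05) stop("`dt_int` must be <= 0.05 ms for stability",
                          call. = FALSE)
  n_in <- length(total_g)
  t_end <- (n_in - 1L) * dt
  tt <- seq(0, t_end, by = dt_int)
  gsyn <- stats::approx(seq(0, t_end, by = dt), total_g, xout = tt)$y
  p <- params
  an <- function(v) 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10))
  bn <- function(v) 0.125 * exp(-(v + 65) / 80)
  am <- function(v) 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10))
  bm <- function(v) 4 * exp(-(v + 65) / 18)
  ah <- function(v) 0.07 * exp(-(v + 65) / 20)
  bh <- function(v) 1 / (1 + exp(-(v + 35) / 10))
  ks_inf <- function(v) 1 / (1 + exp(-(v + 35) / 6))
  v <- -65   # near the resting point of the full conductance set
  m <- am(v) / (am(v) + bm(v)); h <- ah(v) / (ah(v) + bh(v))
  nn <- an(v) / (an(v) + bn(v)); ks <- ks_inf(v)
  nt <- length(tt)
  vout <- numeric(nt); vout[1L] <- v
  spikes <- numeric(0)
  armed <- TRUE
  for (i in 2:nt) {
    ina <- p$g_na * m^3 * h * (p$e_na - v)
    ik <- p$g_kdr * nn^4 * (p$e_k - v)
    iks <- p$g_ks * ks * (p$e_k - v)
    il <- p$g_leak * (p$e_leak - v)
    isyn <- gsyn[i - 1L] * (p$e_syn - v)
    v_new <- v + dt_int * (ina + ik + iks + il + isyn) / p$c_m
    if (!is.finite(v_new) || abs(v_new) > 500) {
      stop("HH integration failure: membrane potential diverged at t = ",
           round(tt[i], 3), " ms", call. = FALSE)
    }
    # exponential-Euler gating (exact for frozen voltage)
    tm_ <- 1 / (am(v) + bm(v)); m_inf <- am(v) * tm_
    th_ <- 1 / (ah(v) + bh(v)); h_inf <- ah(v) * th_
    tn_ <- 1 / (an(v) + bn(v)); n_inf <- an(v) * tn_
    m <- m_inf + (m - m_inf) * exp(-dt_int / tm_)
    h <- h_inf + (h - h_inf) * exp(-dt_int / th_)
    nn <- n_inf + (nn - n_inf) * exp(-dt_int / tn_)
    ks <- ks_inf(v) + (ks - ks_inf(v)) * exp(-dt_int / p$tau_ks)
    v <- v_new
    vout[i] <- v
    if (armed && v >= -20) {
      spikes <- c(spikes, tt[i])
      armed <- FALSE
    } else if (!armed && v <= -40) {
      armed <- TRUE
    }
  }
  list(spikes = structure(spikes, class = "spike_train", refractory = 0),
       t = tt, v = vout)
}

#' Gaussian smoothing of a uniformly sampled series
#'
#' Convolution with a Gaussian kernel of SD `sd_ms`, truncated at 4 SD,
#' with edge correction (division by the in-window kernel mass) so the
#' series keeps its scale at the boundaries. The experiments apply this to
#' the rate readout with the same default SD as [estimate_firing_rate()],
#' so rate-based and spike-based readouts enter the coding analysis with
#' matched temporal resolution.
#'
#' @param x numeric series on a uniform grid.
#' @param sd_ms kernel SD in ms.
#' @param dt grid step in ms.
#' @return Smoothed series, same length.
#' @export
gaussian_smooth <- function(x, sd_ms, dt = 1) {
  stopifnot_scalar_pos(sd_ms, "sd_ms")
  n <- length(x)
  half <- ceiling(4 * sd_ms / dt)
  kt <- (-half:half) * dt
  kern <- exp(-kt^2 / (2 * sd_ms^2))
  kern <- kern / sum(kern)
  zeros <- rep(0, half)
  num <- stats::filter(c(zeros, x, zeros), kern, sides = 2)
  mass <- stats::filter(c(zeros, rep(1, n), zeros), kern, sides = 2)
  keep <- (half + 1L):(half + n)
  as.numeric(num[keep] / mass[keep])
}

#' Gaussian-kernel firing-rate estimate from a spike train
#'
#' Bins spikes at `dt` and convolves with a Gaussian kernel of SD
#' `kernel_sd` ms, with edge correction (division by the kernel mass that
#' falls inside the recording) so the time integral of the estimate equals
#' the spike count.
#'
#' @param spikes spike times, ms.
#' @param duration series duration, ms.
#' @param dt output grid step, ms.
#' @param kernel_sd Gaussian SD, ms.
#' @return Firing-rate series in Hz on the grid `seq(0, duration, by = dt)`.
#' @export
estimate_firing_rate <- function(spikes, duration, dt = 1, kernel_sd = 50) {
  stopifnot_scalar_pos(kernel_sd, "kernel_sd")
  tg <- seq(0, duration, by = dt)
  n <- length(tg)
  counts <- tabulate(pmin(n, floor(as.numeric(spikes) / dt) + 1L),
                     nbins = n)
  1000 / dt * gaussian_smooth(counts, kernel_sd, dt)
}
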