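---
title: "From head direction to head speed: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From head direction to head speed: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hdspeed` simulates a thalamo-retrosplenial circuit in which an ensemble of
anterior-thalamic head-direction (HD) cells drives a single low-rheobase (LR)
retrosplenial neuron through short-term-depressing synapses, and asks what the
postsynaptic firing rate encodes. The central claim the package makes testable
is that **synaptic depression converts a pure direction code into an angular
head speed code**: HD cells are tuned only to direction, yet the LR readout
rate tracks how fast the head is turning.

This vignette explains the model stage by stage, states every tunable that
matters with its default and rationale, and is explicit about what the
synthetic data can and cannot show.

## The presynaptic HD population

Each HD cell fires around a preferred angle (PA) with the Gaussian-shaped
circular tuning curve

$$f(\theta) = (f_{max} - f_{bg})\, e^{\epsilon(\cos\theta - 1)} + f_{bg},$$

where $f_{bg}$ is the background rate (Hz), $f_{max}$ the peak rate (Hz) and
$\epsilon$ a dimensionless concentration (larger is narrower). Cells are
heterogeneous: each parameter is drawn independently from a shifted, scaled
Beta distribution (`beta_spec()`), and pairs with $f_{max} < f_{bg}$ are
redrawn jointly. The exact Beta quantities used in the original study are
tabulated in supplementary material that is not reproduced here, so the
package defaults are **provisional** choices matching the reported
anterodorsal-thalamus summary statistics and are fully config-exposed:

| parameter  | default            | support       | mean    |
|------------|--------------------|---------------|---------|
| $f_{bg}$   | Beta(2, 4)         | [0, 10] Hz    | 3.3 Hz  |
| $f_{max}$  | Beta(3, 3)         | [20, 100] Hz  | 60 Hz   |
| $\epsilon$ | Beta(2, 4)         | [1, 9]        | 3.7     |
| ATI        | Beta(2, 2)         | [0, 100] ms   | 50 ms   |

The mean anticipatory time interval (ATI) of 50 ms follows the reported
anterior-thalamus range (25–50 ms). Spikes are drawn from an inhomogeneous
Poisson process with intensity $r(t) = f(\mathrm{pa} - \theta_A(t))$, thinned
against the cell's maximum rate, with an absolute 4 ms dead time imposed by
discarding candidates within 4 ms of the last accepted spike (equivalent to
silencing the intensity for 4 ms after each spike).

### Anticipatory firing

An HD cell with ATI $A$ effectively experiences the trajectory
$\theta_A(t) = \theta_T(t) + A\,\dot\theta_T(t)$: during a turn at angular
velocity $\omega$ its PA shifts by $-\omega A$, i.e. the cell fires $A$ ms
before the head reaches its PA. The package implements anticipation exactly
in this trajectory-transform form, with the angular velocity computed once
and shared across cells.

## Synthetic head-direction trajectories

Real head tracking is sampled at a low rate (about 40 Hz) and linearly
interpolated onto the fine simulation grid. The synthetic generator
(`ou_trajectory()`) emulates exactly that pipeline: angular velocity follows
a stationary Ornstein–Uhlenbeck (OU) process advanced with its exact
discrete-time update on the 40 Hz raw grid, the angle is integrated with the
left-endpoint rule (so that the centered-difference derivative of the
interpolated angle recovers the velocity process without attenuation), and
the angle is then linearly interpolated to the `dt` grid like a real
tracking table would be.

Defaults, chosen once as representative of mouse head movement and **not**
revisited: relaxation time $\tau_\omega = 200$ ms, stationary SD
$\sigma_\omega = 2$ rad/s (about 115°/s), raw rate 40 Hz, fine step
`dt = 1` ms (fine enough for the 4 ms refractory period and all synaptic
time constants). Angular velocity uses the standard centered difference on
the *unwrapped* angle — differentiating wrapped angles produces $2\pi$
spikes — with one-sided differences at the two boundary samples so series
keep full length for lag analysis.

What the OU generator reproduces: realistic speed magnitudes, smooth
velocity with a behavioral correlation time, interleaved slow and fast
epochs, and the low-rate-tracking interpolation structure. What it does not
reproduce: the heavy-tailed bout structure of real rodent turning
(stillness punctuated by discrete saccade-like turns), head nods, tracking
noise, or any coupling between speed and position. Conclusions that depend
on the detailed shape of the speed distribution — most notably the exact
optimal lag, and the coincidence of the correlation- and MI-optimal lags
discussed below — should therefore be read as conditional on this
trajectory model.

## The depressing synapse

Short-term plasticity follows the Tsodyks–Markram (TM) three-variable model:
vesicle pool $x$, release probability $u$, conductance $g$, with
between-spike dynamics

$$\dot x = \frac{1-x}{\tau_d}, \qquad \dot u = -\frac{u}{\tau_f}, \qquad
  \dot g = -\frac{g}{\tau_g},$$

and, at each presynaptic spike, $u^+ = u^- + U(1-u^-)$, a release
$u^+ x^-$, the depletion $x^+ = x^-(1 - u^+)$, and a conductance jump of
$A\,u^+x^-$ with synaptic weight $A$. The implementation is event-driven
and exact: states relax in closed form between spikes, so there is no
integration error to accumulate, and a brute-force RK4 integration of the
ODE system at 0.01 ms serves as the test oracle.

The depressing thalamocortical synapse uses $\tau_d = 270$ ms,
$\tau_f = 40$ ms, $U = 0.28$ — the parameter set obtained by exhaustive
grid search against 10 Hz pulse-train EPSP amplitudes (`fit_tm()`
reproduces this workflow; the shipped amplitude file is synthetic,
regenerated from these parameters, because the raw recordings are not
redistributable here). With $\tau_f \ll \tau_d$ the synapse is
depression-dominated. The fitting grid default
($\tau_d \in [10, 1000]$ by 10, $\tau_f \in [5, 500]$ by 5,
$U \in [0.02, 0.98]$ by 0.02) brackets the optimum at a resolution
consistent with its significant figures; ties break lexicographically for
determinism. The fit targets normalized amplitudes (first pulse $=1$); the
weight is recoverable separately from the raw first amplitude.

The conductance decay $\tau_g$ is **not** part of the fitted set and is not
reported with it; the package default is 10 ms. Because $\tau_g$ adds group
delay to the readout, the optimal-lag results are reported together with a
sensitivity analysis (below). The non-depressing control synapse is a
standard exponential synapse whose jump is fixed at $A \cdot U$, matching
the rested first-pulse amplitude of the depressing synapse, so both modes
deliver identical drive statistics at rest.

## The postsynaptic readout

The reference readout is deliberately simple: the summed conductance of all
synapses (point summation; dendritic placement is not modeled) is low-pass
filtered with a membrane time constant $\tau_m = 10$ ms and affinely mapped
to a rate. All coding scores used downstream (Pearson correlation, mutual
information, Spearman rank correlations) are invariant to the affine map,
so `gain` and `baseline` are reporting conveniences, not science. A
conductance-driven Hodgkin–Huxley point neuron (fast Na, delayed-rectifier
K, and a slow non-inactivating K current standing in for the Kv1.1
component that shapes LR excitability) is provided as a secondary readout;
the package tests check that both readouts order the synapse modes
identically, and the morphologically detailed LR model of the original
study is intentionally out of scope.

Because a spike-based readout only ever enters analysis as a
kernel-smoothed rate estimate (Gaussian kernel, SD 50 ms by default), the
experiments apply the *same* 50 ms smoothing to the rate readout
(`kernel_sd` argument, `NULL` to disable). This keeps the two readout
routes comparable and sets the temporal resolution of all lag results.

## Coding analysis

For series $x_t$ (postsynaptic rate) and $y_t$ (angular head speed), the
lagged similarity at lag $l$ pairs $x_t$ with $y_{t+l}$, so a delayed copy
$y_t = x_{t-L}$ peaks at $l = L$, and a *negative* optimal lag means the
rate tracks past speed. Two measures are used on the same lag grid
(default $-70$ to $70$ ms in 2 ms steps): Pearson correlation, and plug-in
mutual information after discretizing each series into 40 equal-width bins
over its observed range. Ties in the argmax break toward the smallest
$|l|$, then the negative lag. Zero-variance overlaps yield `NA` markers,
never silent zeros.

Direction coding uses the mutual information between the binned rate and
the wrapped direction (40 bins), plus a circular–linear correlation
(the correlation of the rate with the best-fitting cosine of direction,
Mardia's formula) — a raw Pearson correlation with an angle would depend
on where the circle is cut. Heterogeneity of a preferred-angle density is
its circular 1-Wasserstein distance from uniform (arc-length ground
metric), computed as the median-centred integral of the CDF difference;
a point mass attains $\pi/2$.

Nonuniform PA densities are built from a standard Brownian bridge $B$ on
$[0, 2\pi]$ used as a random *log*-density: density
$\propto e^{\rho B(\theta)}$, which is positive and $2\pi$-periodic by
construction; $\rho$ (`roughness`) is the amplitude. Inverse-transform
sampling draws PAs from the density. Exponentiation was chosen over
clipping or offsetting a bridge because it guarantees positivity without
flat censored regions; the package treats this as an interpretation and
documents it as such. For the population experiment, per-cell roughness is
drawn uniformly on $[0, 1.2]$, which spans Wasserstein heterogeneities of
roughly 0–0.5 rad.

## The three experiments

* `run_speed_coding()` — one trajectory, one ensemble, both synapse modes
  on the *same* spike trains, so the contrast isolates synaptic dynamics.
  Desk-scale defaults: 1000 HD cells, 120 s, `dt = 1` ms (the original
  study uses 7500 cells with a robustness check at 2500, which the
  acceptance checks reproduce at 2500).
* `run_ati_sweep()` — the speed-coding run repeated with all ATIs clamped
  to each value of a sweep; trajectory, tuning-parameter draws and
  per-cell RNG streams are shared across arms, so residual cross-arm
  variance is spike sampling only.
* `run_population_tradeoff()` — a population of LR cells (default 50),
  each with an independent bridge-mode PA draw, scored for heterogeneity
  (WD) and for speed/direction coding.

Per-cell RNG streams are spawned from one master seed, so results do not
depend on iteration order or on how many cells precede a given cell.
Aggregation bins each synapse's conductance jumps on the `dt` grid before
applying the shared $\tau_g$ decay; with `dt = 1` ms
$\ll \tau_g$ the binning error is negligible relative to spike sampling.

## The mean-field reduction

Replacing the spiking ensemble with a continuum of preferred angles gives a
depression field $x(\theta, t)$ with

$$\frac{\partial x}{\partial t} = \frac{1 - x}{\tau_d}
  - U\,x\,f(\theta - \theta_A(t)),$$

drive $D(t) = U \int x\,f\,d\theta$, and a first-order postsynaptic
integrator. Facilitation is dropped because $\tau_f \ll \tau_d$ at the
fitted point. Integration is operator splitting per `dt` with *exact*
sub-flows (depletion factor $e^{-U f\,dt}$, then linear relaxation), on a
256-point angular grid with an aliasing guard tied to the tuning width;
doubling the resolution changes the drive by well under 0.1%.

The reduction makes three claims checkable without sampling noise:
(1) at rest the drive settles to a fixed point and at constant rotation to
a rotating steady state increasing with speed; (2) the low-speed excess
drive $D(\omega) - D(0)$ scales as $\omega^2$ (the measured log–log
exponent is 1.99, and the speed–drive curve is concave up), explaining the
parabolic speed–rate relationship; (3) anticipation compensates the
integration lag: the optimal lag between the mean-field rate and speed
shrinks toward zero as the ATI grows toward the circuit's effective
integration time. A cross-route test also checks the reduction against the
stochastic ensemble: at constant rotation with matched homogeneous
parameters the stationary ensemble conductance matches
$(N/2\pi)\,D\,\tau_g/1000$ within Monte-Carlo error.

## Numerical choices and degenerate inputs

* Simulation step `dt = 1` ms everywhere by default; trajectory loading
  errors on non-monotone times or fewer than two samples.
* `sigma_omega = 0` degenerates to a constant heading (and an exactly zero
  velocity); `roughness = 0` degenerates to the uniform PA density.
* Empty spike trains produce identically zero conductance; empty speed
  bins are kept but marked; cells never active (or with zero variance in
  their active window) are excluded from the active-window correlation
  with their count reported.
* The Wasserstein score validates normalization to $10^{-6}$ before
  computing; lag grids must be multiples of `dt`.

## Known limitations

* The corr-optimal and MI-optimal lags of the depressing-mode speed code
  do **not** coincide under the OU trajectory at desk scale: across the
  full sensitivity grid ($\tau_g \in \{5, 10, 20\}$ ms,
  $\tau_m \in \{5, 10\}$ ms, kernel SD $\in \{10, 25, 50\}$ ms) the
  correlation lag sits 12–22 ms deeper in the past than the MI lag, and
  the same offset appears in the noise-free mean-field rate, so it is a
  structural property of this nonlinear filter under these trajectory
  statistics, not sampling noise. Both lag curves are broad plateaus
  (the correlation changes by less than $10^{-3}$ over 10 ms around its
  maximum). The package reports both lags rather than forcing agreement.
* The exact optimal-lag value depends on $\tau_g$, $\tau_m$ and the
  smoothing kernel (roughly 20 ms of spread across the grid above), none
  of which are constrained by the available measurements; treat reported
  lags as resolution-limited.
* Speed *mutual information* in the population experiment does not fall
  with heterogeneity the way the speed correlation does (direction-driven
  rate structure contributes dependence); the tradeoff claim is carried by
  the correlation score, and both are reported.
* HD cells are conditionally independent given the trajectory; attractor
  dynamics, bursting, adaptation, feedforward inhibition and dendritic
  placement are out of scope.

## Problem sizes

The package's default experiment sizes (1000 HD cells for 120 s; 50 LR
cells at 400 inputs for 60 s; 2500 cells for the robustness check) were
chosen as the smallest sizes at which every qualitative contrast above is
stable across seeds; all of them are arguments, and the study-scale sizes
(7500 cells, 200 LR cells, 600 s) run unchanged if given time.
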