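test_that("tm_relax follows the closed-form between-spike solution", {
  p <- tm_params()
  s0 <- tm_state(x = 0.72, u = 0.3, g = 2)
  expect_equal(tm_relax(s0, 0, p)[c("x", "u", "g")],
               s0[c("x", "u", "g")])
  s1 <- tm_relax(s0, 100, p)
  expect_equal(s1$x, 1 - 0.28 * exp(-100 / 270), tolerance = 1e-12)
  expect_equal(s1$x, 0.8067, tolerance = 1e-3)
  expect_equal(s1$u, 0.3 * exp(-100 / 40), tolerance = 1e-12)
  expect_equal(s1$g, 2 * exp(-100 / 10), tolerance = 1e-12)
  s_inf <- tm_relax(s0, 1e7, p)
  expect_equal(c(s_inf$x, s_inf$u, s_inf$g), c(1, 0, 0), tolerance = 1e-12)
  expect_error(tm_relax(s0, -1, p), ">= 0")
})

test_that("tm_spike applies the jump relations; u+ >= U always", {
  p <- tm_params()
  rest <- tm_spike(tm_state(), p)
  expect_equal(rest$release, 0.28)
  expect_equal(rest$state$x, 1 - 0.28)
  expect_equal(rest$state$u, 0.28)
  expect_equal(rest$state$g, 0.28 * p$weight)

  # facilitation-off limit: u- ~ 0 before every spike, so u+ = U each time
  p_dep <- tm_params(tau_f = 1e-6)
  rel <- hdspeed:::tm_releases(seq(0, 900, by = 100), p_dep)
  st <- tm_state()
  for (k in 1:10) {
    st <- tm_relax(st, if (k == 1) 0 else 100, p_dep)
    out <- tm_spike(st, p_dep)
    expect_equal(out$state$u, p_dep$U, tolerance = 1e-9)
    st <- out$state
  }

  # second/first release ratio at 10 Hz for the fitted parameters
  rel2 <- hdspeed:::tm_releases(c(0, 100), tm_params())
  expect_equal(rel2[2L] / rel2[1L], 0.8543, tolerance = 2e-4)
})

test_that("state bounds hold along arbitrary spike trains", {
  p <- tm_params(tau_d = 150, tau_f = 300, U = 0.4)
  set.seed(8)
  times <- sort(runif(300, 0, 3000))
  st <- tm_state()
  for (ts in times) {
    st <- tm_relax(st, ts - st$t_last, p)
    out <- tm_spike(st, p)
    st <- out$state
    expect_true(st$x >= 0 && st$x <= 1)
    expect_true(st$u >= p$U - 1e-12 && st$u <= 1)
    expect_true(out$release >= 0)
  }
})

test_that("event-driven dynamics match brute-force RK4 integration", {
  p <- tm_params()
  dt_ode <- 0.01
  n_steps <- 30e3                      # 300 ms per train
  set.seed(13)
  spike_steps <- lapply(1:10, function(i) {
    k <- rpois(1, 6) + 1L
    sort(sample.int(n_steps - 100L, k))
  })
  rec_steps <- seq(0L, n_steps, by = 1000L)   # every 10 ms
  oracle <- tm_rk4_oracle(spike_steps, p, n_steps, dt_ode, rec_steps)
  for (i in seq_along(spike_steps)) {
    ed <- tm_states_on_grid(spike_steps[[i]] * dt_ode, p,
                            rec_steps * dt_ode)
    expect_lt(max(abs(ed - oracle[i, , ])), 1e-6)
  }
})

test_that("conductance train: empty, single-spike, and 10 Hz depression profile", {
  p <- tm_params()
  empty <- conductance_train(numeric(0), p, dt = 1, duration = 50)
  expect_true(all(empty$g == 0))

  one <- conductance_train(10, p, dt = 0.5, duration = 100)
  expect_equal(max(one$g), p$weight * p$U, tolerance = 1e-9)
  i10 <- which(one$t == 10)
  expect_equal(one$g[i10 + 20L] / one$g[i10], exp(-10 / p$tau_g),
               tolerance = 1e-9)
  expect_true(all(one$g[one$t < 10] == 0))

  train <- conductance_train(seq(0, 900, by = 100), p)
  expect_equal(train$amplitudes[1L], 1)
  expect_true(all(diff(train$amplitudes) < 0))   # monotone depression
  # approaching the analytic steady state from above
  ss <- tm_steady_state(10, p)
  expect_true(all(train$releases > ss$release_ss))
})

test_that("steady-state formula agrees with long-run event-driven simulation", {
  p <- tm_params()
  long <- conductance_train(seq(0, by = 100, length.out = 100), p)
  ss <- tm_steady_state(10, p)
  expect_equal(long$releases[100L], ss$release_ss, tolerance = 1e-9)

  # vanishing rate: full recovery between pulses
  slow <- tm_steady_state(1e-4, p)
  expect_equal(slow$x_ss, 1, tolerance = 1e-9)
  expect_equal(slow$release_ss, p$U, tolerance = 1e-9)

  # release_ss strictly decreasing in rate for depression-dominant params
  rates <- c(1, 2, 5, 10, 20, 40)
  rel <- vapply(rates, function(r) tm_steady_state(r, p)$release_ss,
                numeric(1))
  expect_true(all(diff(rel) < 0))
  # 40 Hz depresses more than 10 Hz
  expect_lt(tm_steady_state(40, p)$release_ss,
            tm_steady_state(10, p)$release_ss)
  expect_error(tm_steady_state(0, p), "positive")
})

test_that("depression-only monotonicity holds whenever tau_f <= tau_d / 5", {
  for (td in c(100, 270, 600)) {
    p <- tm_params(tau_d = td, tau_f = td / 5, U = 0.3)
    amps <- conductance_train(seq(0, 900, by = 100), p)$amplitudes
    expect_true(all(diff(amps) <= 1e-12))
  }
})

test_that("exponential control synapse: identical jumps, TM limit, empty train", {
  st <- c(5, 9, 12, 80)
  es <- exp_synapse(st, weight = 2, tau_g = 10, dt = 0.5)
  # jump at each spike equals the weight regardless of ISI history
  for (ts in st) {
    i <- which(es$t == ts)
    before <- if (i > 1L) es$g[i - 1L] * exp(-0.5 / 10) else 0
    expect_equal(es$g[i] - before, 2 * exp(-(es$t[i] - ts) / 10),
                 tolerance = 1e-9)
  }
  expect_true(all(exp_synapse(numeric(0), 1, 10, duration = 20)$g == 0))

  # TM with instantaneous recovery and no facilitation reduces to the
  # exponential synapse with weight' = weight * U
  p_lim <- tm_params(tau_d = 1e-4, tau_f = 1e-4, tau_g = 10, U = 0.4,
                     weight = 5)
  tm_g <- conductance_train(st, p_lim, dt = 0.5, duration = 120)$g
  ex_g <- exp_synapse(st, weight = 5 * 0.4, tau_g = 10, dt = 0.5,
                      duration = 120)$g
  expect_equal(tm_g, ex_g, tolerance = 1e-6)
})

test_that("grid-search fit recovers generating parameters and handles flat trains", {
  p_true <- tm_params(tau_d = 270, tau_f = 40, U = 0.28)
  amps <- conductance_train(seq(0, 900, by = 100), p_true)$amplitudes
  fit <- fit_tm(amps, isi = 100,
                grid = list(tau_d = seq(200, 350, by = 10),
                            tau_f = seq(20, 80, by = 5),
                            U = seq(0.2, 0.4, by = 0.02)))
  expect_equal(fit$tau_d, 270)
  expect_equal(fit$tau_f, 40)
  expect_equal(fit$U, 0.28)
  expect_lt(attr(fit, "loss"), 1e-12)

  # flat normalized train: best fit shows essentially no depression
  flat <- fit_tm(rep(1, 10), isi = 100,
                 grid = list(tau_d = seq(10, 200, by = 10),
                             tau_f = seq(5, 100, by = 5),
                             U = seq(0.02, 0.5, by = 0.02)))
  model <- attr(flat, "fitted")
  expect_lt(1 - model[10L] / model[1L], 0.05)

  expect_error(fit_tm(1), "at least 2")
})
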