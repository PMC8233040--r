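test_that("tuning curve matches its closed form and basic shape", {
  expect_equal(tuning_curve(0, 1, 40, 4), 40)
  expect_equal(tuning_curve(pi, 1, 40, 4), 39 * exp(-8) + 1,
               tolerance = 1e-12)
  expect_equal(tuning_curve(pi, 1, 40, 4), 1.0131, tolerance = 1e-4)
  # vanishing modulation
  expect_equal(tuning_curve(seq(0, 2 * pi, 0.1), 5, 5, 3),
               rep(5, 63))
  th <- seq(-pi, pi, length.out = 201)
  f <- tuning_curve(th, 2, 30, 5)
  expect_equal(f, rev(f))                        # symmetry
  expect_equal(f, tuning_curve(th + 2 * pi, 2, 30, 5))  # periodicity
  up <- tuning_curve(seq(0, pi, length.out = 100), 2, 30, 5)
  expect_true(all(diff(up) < 0))                 # decreasing on [0, pi]
  expect_true(all(f >= 2 & f <= 30))
})

test_that("Beta sampling honors support, mean and determinism", {
  sp <- beta_spec(2, 5, loc = 10, scale = 20)
  x <- sample_beta(sp, 1e4, seed = 1)
  expect_true(all(x >= 10 & x <= 30))
  expect_lt(abs(mean(x) - (10 + 20 * 2 / 7)), 0.15)
  expect_identical(x, sample_beta(sp, 1e4, seed = 1))

  u <- sample_beta(beta_spec(1, 1), 1e4, seed = 2)
  expect_gt(suppressWarnings(ks.test(u, "punif")$p.value), 0.01)

  expect_error(beta_spec(-1, 1), "positive")
  expect_error(beta_spec(1, 1, scale = 0), "positive")
})

test_that("ensemble sampling enforces constraints and reproducibility", {
  spec <- ensemble_spec(n_cells = 2000, seed = 9)
  ens <- sample_ensemble(spec)
  expect_equal(nrow(ens), 2000)
  expect_true(all(ens$f_max >= ens$f_bg))
  expect_true(all(ens$f_bg >= 0))
  expect_true(all(ens$pa >= 0 & ens$pa < 2 * pi))
  expect_lt(abs(mean(ens$ati) - 50), 2)
  expect_identical(ens$pa, sample_ensemble(spec)$pa)

  fixed <- ensemble_spec(n_cells = 50, ati_fixed = 0, seed = 1)
  expect_true(all(sample_ensemble(fixed)$ati == 0))
})

test_that("cell rate series peaks early by ati during constant rotation", {
  cell <- list(f_bg = 1, f_max = 40, epsilon = 6, ati = 50, pa = pi)
  omega <- 2
  tr <- const_rotation_traj(omega, 4000)
  r <- cell_rate_series(cell, tr)
  # rate must peak when theta_T = pa - omega * A (the PA shift property)
  peak_theta <- tr$theta[which.max(r[2:(length(r) - 1L)]) + 1L]
  expect_lt(abs(peak_theta - (pi - omega * 0.050)), 0.01)

  # constant heading at the PA: rate pinned at f_max for any ati
  cst <- const_heading_traj(pi, 500)
  expect_equal(cell_rate_series(cell, cst), rep(40, 501))

  # equivalent formulation: ati = A equals a cell with shifted PA, ati = 0
  shifted <- list(f_bg = 1, f_max = 40, epsilon = 6, ati = 0,
                  pa = pi - omega * 0.050)
  idx <- 2:(length(tr$t) - 1L)
  expect_equal(cell_rate_series(cell, tr)[idx],
               cell_rate_series(shifted, tr)[idx], tolerance = 1e-10)
})

test_that("with ati = 0 CW and CCW passes give identical tuning; with ati > 0 they shift apart", {
  dur <- 6000
  ccw <- const_rotation_traj(1, dur)
  cw <- const_rotation_traj(-1, dur)
  idx <- 2:(dur - 1L)
  tuning_of <- function(cell, tr) {
    r <- cell_rate_series(cell, tr)[idx]
    th <- wrap_angle(tr$theta[idx])
    list(theta = th, r = r)
  }
  cell0 <- list(f_bg = 1, f_max = 40, epsilon = 6, ati = 0, pa = pi)
  t_ccw <- tuning_of(cell0, ccw); t_cw <- tuning_of(cell0, cw)
  # same rate at the same wrapped heading regardless of turn direction
  o1 <- order(t_ccw$theta); o2 <- order(t_cw$theta)
  expect_equal(approx(t_ccw$theta[o1], t_ccw$r[o1], xout = 3)$y,
               approx(t_cw$theta[o2], t_cw$r[o2], xout = 3)$y,
               tolerance = 1e-6)
  cellA <- list(f_bg = 1, f_max = 40, epsilon = 6, ati = 50, pa = pi)
  peak_at <- function(tr) {
    r <- cell_rate_series(cellA, tr)[idx]
    wrap_angle(tr$theta[idx][which.max(r)])
  }
  # CCW peak at pa - omega*A, CW peak at pa + omega*A
  expect_lt(abs(peak_at(ccw) - (pi - 0.05)), 0.01)
  expect_lt(abs(peak_at(cw) - (pi + 0.05)), 0.01)
})

test_that("spike generator: empty at zero rate, refractory respected, dead-time rate law", {
  expect_length(generate_spike_train(rep(0, 1000), 1, seed = 1), 0)

  r <- rep(50, 200e3)  # 50 Hz for 200 s
  st <- generate_spike_train(r, 1, refractory = 4, seed = 11)
  expect_true(all(diff(st) >= 4))
  # renewal oracle: Poisson with dead time fires at lambda/(1 + lambda d)
  expected <- 50 / (1 + 50 * 0.004)
  emp <- length(st) / 200
  expect_lt(abs(emp - expected) / expected, 0.03)

  expect_error(generate_spike_train(c(-1, 2), 1), "nonnegative")
  expect_identical(generate_spike_train(rep(20, 1e4), 1, seed = 3),
                   generate_spike_train(rep(20, 1e4), 1, seed = 3))
})

test_that("spike generator passes the time-rescaling test without dead time", {
  dt <- 1
  t <- seq(0, 60e3, by = dt)
  rate <- 20 + 15 * sin(2 * pi * t / 5000)
  st <- generate_spike_train(rate, dt, refractory = 0, seed = 21)
  cum <- cumsum(rate) * dt / 1000         # integrated intensity
  lam <- approx(t, cum, xout = st)$y
  isis <- diff(lam)
  p <- suppressWarnings(ks.test(isis, "pexp")$p.value)
  expect_gt(p, 0.01)
})

test_that("preferred-angle densities normalize, sample correctly, and score heterogeneity", {
  u <- sample_pa(500, mode = "uniform", seed = 2)
  expect_true(all(u$pa >= 0 & u$pa < 2 * pi))
  expect_equal(hdspeed:::trapz(u$density$grid, u$density$density), 1,
               tolerance = 1e-9)
  expect_equal(wasserstein_to_uniform(u$density), 0, tolerance = 1e-12)

  # roughness 0 degenerates to uniform
  b0 <- sample_pa(100, mode = "bridge", roughness = 0, seed = 3)
  expect_equal(b0$density$density, u$density$density)

  b <- sample_pa(1e5, mode = "bridge", roughness = 1.5, seed = 4)
  d <- b$density
  expect_equal(hdspeed:::trapz(d$grid, d$density), 1, tolerance = 1e-9)
  expect_equal(d$density[1L], d$density[length(d$density)],
               tolerance = 1e-9)           # periodic
  expect_true(all(d$density >= 0))

  # inverse-transform correctness: chi-square GOF of samples against the
  # sampling law implied by the density's piecewise-linear CDF
  edges <- seq(0, 2 * pi, length.out = 37)
  counts <- table(cut(b$pa, edges))
  m <- length(d$grid)
  cdf <- c(0, cumsum((d$density[-1L] + d$density[-m]) / 2 * diff(d$grid)))
  cdf <- cdf / cdf[m]
  probs <- diff(approx(d$grid, cdf, xout = edges)$y)
  probs <- probs / sum(probs)
  p <- suppressWarnings(chisq.test(as.numeric(counts), p = probs)$p.value)
  expect_gt(p, 0.001)
})

test_that("Wasserstein score: point mass limit, rotation invariance, monotone in roughness", {
  # near-point-mass density: wrapped Gaussian with tiny SD -> wd ~ pi/2
  grid <- seq(0, 2 * pi, length.out = 4097)
  dens <- dnorm(grid, mean = pi, sd = 0.01)
  dens <- dens / hdspeed:::trapz(grid, dens)
  wd <- wasserstein_to_uniform(list(grid = grid, density = dens))
  expect_lt(abs(wd - pi / 2), 0.02)

  # rotation invariance (wrap the same narrow bump elsewhere)
  dens2 <- dnorm(grid, mean = 1, sd = 0.01) + dnorm(grid, mean = 1 + 2 * pi,
                                                    sd = 0.01)
  dens2 <- dens2 / hdspeed:::trapz(grid, dens2)
  wd2 <- wasserstein_to_uniform(list(grid = grid, density = dens2))
  expect_lt(abs(wd2 - wd), 0.02)

  expect_error(wasserstein_to_uniform(list(grid = grid, density = dens * 3)),
               "integrate")

  # increasing roughness increases expected heterogeneity
  mean_wd <- function(r) {
    mean(vapply(1:8, function(s) {
      wasserstein_to_uniform(sample_pa(1, "bridge", roughness = r,
                                       seed = s)$density)
    }, numeric(1)))
  }
  expect_true(mean_wd(0.3) < mean_wd(1) && mean_wd(1) < mean_wd(2.5))
})
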