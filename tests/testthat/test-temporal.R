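test_that("geometric time-constant series follows tau_k = c^{2(k-K)} tau_max", {
  b <- geometric_time_constants(4, sqrt(2), 16)
  expect_equal(b$taus, c(2, 4, 8, 16))
  expect_equal(b$mus, c(sqrt(2), 2, 2 * sqrt(2), 4))
  expect_equal(geometric_time_constants(1, 2, 7)$taus, 7)
  # geometric ratio invariant
  b2 <- geometric_time_constants(6, 1.3, 5)
  expect_equal(b2$taus[-1] / b2$taus[-6], rep(1.3^2, 5))
  expect_error(geometric_time_constants(0, 2, 1))
})

test_that("endpoint-pinned grid spans [1, 4] logarithmically", {
  b <- time_constant_grid(1, 4, 4)
  expect_equal(b$mus, c(1, 4^(1 / 3), 4^(2 / 3), 4))
  expect_equal(time_constant_grid(1, 4, 1)$mus, 4)
})

test_that("truncated exponential kernel is causal and normalized", {
  expect_equal(h_exp(c(-1, 0), 2), c(0, 0))
  expect_equal(h_exp(2, 2), exp(-1) / 2)
  dt <- 1e-3
  tt <- seq(dt, 40, by = dt)
  expect_lt(abs(sum(h_exp(tt, 1.7)) * dt - 1), 1e-3)
})

test_that("leaky integrator decays, converges and retains e^{-4} after 8 steps at mu = 2", {
  # homogeneous decay at fine dt
  dt <- 1e-3
  u <- li_evolve(rep(0, 5000), mu = 1, dt = dt, u0 = 1)
  expect_lt(max(abs(u - exp(-seq_len(5000) * dt))), 1e-3)
  # fixed point under constant drive
  u2 <- li_evolve(rep(5, 200), mu = 2, dt = 1)
  expect_equal(tail(u2, 1), 5, tolerance = 1e-8)
  # impulse retention: mu = 2, 8 unit steps (exact under exponential Euler)
  u3 <- li_evolve(rep(0, 8), mu = 2, dt = 1, u0 = 1)
  expect_equal(u3[8], exp(-4))
  expect_warning(li_evolve(rep(0, 3), mu = 0.5, dt = 1), "dt >= mu")
})

test_that("leaky integrator is linear and converges to the h_exp convolution", {
  set.seed(1)
  f1 <- rnorm(300); f2 <- rnorm(300)
  a <- 1.7; b <- -0.6
  expect_equal(li_evolve(a * f1 + b * f2, 3),
               a * li_evolve(f1, 3) + b * li_evolve(f2, 3),
               tolerance = 1e-12)
  # L-inf error vs the exact continuum convolution at least halves when dt
  # halves; the reference is the closed form of (h_exp * gaussian)(t):
  # int_0^t (1/mu) e^{-(t-s)/mu} e^{-(s-c)^2/(2*s0^2)} ds
  mu <- 1; c0 <- 3; s0 <- 0.5
  exact <- function(t) {
    pref <- exp(-(t - c0) / mu + s0^2 / (2 * mu^2)) * s0 * sqrt(2 * pi) / mu
    pref * (pnorm((t - c0 - s0^2 / mu) / s0) - pnorm((-c0 - s0^2 / mu) / s0))
  }
  sig <- function(t) exp(-(t - c0)^2 / (2 * s0^2))
  errs <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    tt <- seq(dt, 8, by = dt)
    max(abs(li_evolve(sig(tt), mu = mu, dt = dt) - exact(tt)))
  }, numeric(1))
  # first-order scheme: the ratio approaches 1/2 from above
  expect_true(all(errs[-1] / errs[-3] <= 0.52))
})

test_that("LIF threshold dynamics: subthreshold silence, closed-form ISI, reset", {
  p <- lif_params(mu = 1, theta_thr = 1, theta_reset = 0, dt = 1e-3)
  # subthreshold: converges to I0 < theta, never spikes
  r <- lif_simulate(rep(0.8, 5000), p)
  expect_equal(sum(r$z), 0)
  # suprathreshold: interspike interval mu ln(I0 / (I0 - theta))
  I0 <- 1.5
  r2 <- lif_simulate(rep(I0, 20000), p)
  isi <- diff(r2$spike_times)
  expect_gt(length(isi), 5)
  expect_equal(mean(isi), 1 * log(I0 / (I0 - 1)), tolerance = 5e-3)
  # reset to theta_reset at the crossing step
  st <- lif_state(1)
  p2 <- lif_params(mu = 1, theta_thr = 1, theta_reset = -0.2, dt = 1)
  st <- lif_step(st, 10, p2)
  expect_equal(st$z, 1L)
  expect_equal(st$u, -0.2)
  expect_equal(st$t_f, 1)
})

test_that("LIF spike count is non-decreasing in input amplitude", {
  p <- lif_params(mu = 2, dt = 0.01)
  set.seed(3)
  base <- pmax(rnorm(2000, 0.5, 0.5), 0)
  counts <- vapply(c(0.5, 1, 2, 4), function(g) {
    sum(lif_simulate(g * base, p)$z)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("spike response model reduces to LI without spikes and resets by theta", {
  p <- lif_params(mu = 2, theta_thr = 1, mu_r = 0.5, dt = 0.01)
  set.seed(4)
  inp <- pmax(rnorm(500, 0.5, 0.3), 0)
  expect_equal(srm_response(inp, -Inf, p), li_evolve(inp, 2, 0.01))
  # at t = t_f the reset contribution is exactly -theta_thr
  u <- srm_response(rep(0, 500), t_f = 1, p)
  expect_equal(u[100], -1)  # t = 1 = t_f
  expect_error(srm_response(inp, 1, lif_params(mu = 2, mu_r = 0, dt = 0.01)),
               "mu_r")
})

test_that("SRM closed form matches the spike-aligned simulated LIF trace", {
  dt <- 0.01
  # soft (subtractive) reset: the after-spike effect relaxes with the
  # membrane constant, i.e. the SRM reset kernel with mu_r = mu
  p <- lif_params(mu = 1, theta_thr = 1, theta_reset = 0, mu_r = 1, dt = dt)
  set.seed(5)
  # Poisson-like pulse drive strong enough to spike a few times
  inp <- rep(0, 1500)
  inp[sample(1500, 120)] <- 3
  inp <- li_evolve(inp, 0.2, dt) * 4
  sim <- lif_simulate(inp, p)
  expect_gt(length(sim$spike_times), 1)
  # reconstruct the trace after the first spike from the SRM closed form
  # (valid until the next spike)
  t1 <- sim$spike_times[1]
  i1 <- round(t1 / dt)
  i2 <- if (length(sim$spike_times) > 1) {
    round(sim$spike_times[2] / dt) - 1
  } else length(inp)
  seg <- (i1 + 1):min(i2, i1 + 80)
  srm <- srm_response(inp, t_f = t1, p)
  scale <- max(abs(sim$u[seg]))
  expect_lt(max(abs(sim$u[seg] - srm[seg])) / scale, 0.05)
})

test_that("the vanishing reset-constant limit reproduces the instantaneous reset", {
  dt <- 1e-3
  drive <- function(t) 1.8 + 0.4 * sin(2 * pi * t / 4)
  tt <- seq(dt, 10, by = dt)
  hard <- lif_simulate(drive(tt), lif_params(mu = 1, mu_r = 0, dt = dt))
  soft <- lif_simulate(drive(tt), lif_params(mu = 1, mu_r = dt, dt = dt))
  expect_equal(length(hard$spike_times), length(soft$spike_times))
  expect_lt(max(abs(hard$spike_times - soft$spike_times)), 5 * dt)
})
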