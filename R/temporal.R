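#' Geometric series of temporal scales / time constants
#'
#' Builds the bank of `K` temporal scales `tau_k = c^{2(k-K)} tau_max`
#' (a geometric series with ratio `c^2`) and the corresponding leaky-integrator
#' time constants `mu_k = sqrt(tau_k)` (timesteps), which jointly give a
#' time-causal, self-similar coverage of temporal scales.
#'
#' @param K number of temporal scale channels (>= 1).
#' @param c distribution parameter (> 1; default `sqrt(2)`).
#' @param tau_max maximum temporal scale (timestep^2 units).
#' @return an object of class `temporal_scale_bank` with fields `K`, `c`,
#'   `tau_max`, `taus`, `mus`.
#' @export
geometric_time_constants <- function(K, c = sqrt(2), tau_max = 16) {
  stopifnot(K >= 1, c > 1, tau_max > 0)
  k <- seq_len(K)
  taus <- c^(2 * (k - K)) * tau_max
  structure(list(K = as.integer(K), c = c, tau_max = tau_max,
                 taus = taus, mus = sqrt(taus)),
            class = "temporal_scale_bank")
}

#' Endpoint-pinned logarithmic grid of time constants
#'
#' Logarithmically distributed time constants with both endpoints pinned:
#' `mu_k = mu_min (mu_max/mu_min)^{(k-1)/(K-1)}`. This is the reading of
#' "logarithmically distributed time constants in the interval [1, 4]" used to
#' initialize the network's temporal scale channels (for `K = 4` it gives
#' `1, 4^{1/3}, 4^{2/3}, 4`); the pure geometric series of
#' [geometric_time_constants()] is available as the alternative convention.
#'
#' @param mu_min,mu_max interval endpoints (timesteps).
#' @param K number of channels.
#' @return a `temporal_scale_bank` (with `c` the implied scale ratio).
#' @export
time_constant_grid <- function(mu_min = 1, mu_max = 4, K = 4L) {
  stopifnot(K >= 1, mu_min > 0, mu_max >= mu_min)
  if (K == 1L) {
    mus <- mu_max
  } else {
    mus <- mu_min * (mu_max / mu_min)^((seq_len(K) - 1) / (K - 1))
  }
  ratio <- if (K > 1) (mu_max / mu_min)^(1 / (K - 1)) else 1
  structure(list(K = as.integer(K), c = ratio, tau_max = mu_max^2,
                 taus = mus^2, mus = mus),
            class = "temporal_scale_bank")
}

#' @export
print.temporal_scale_bank <- function(x, ...) {
  cat(sprintf("temporal scale bank: K=%d, mu = %s timesteps\n",
              x$K, paste(signif(x$mus, 4), collapse = ", ")))
  invisible(x)
}

#' Truncated exponential temporal scale-space kernel
#'
#' The one-sided kernel `h(t; mu) = (1/mu) exp(-t/mu)` for `t > 0` and `0` for
#' `t <= 0`: the only time-causal smoothing kernel family that guarantees
#' non-creation of new structure from finer to coarser temporal scales. It has
#' unit integral over `(0, Inf)` and corresponds to the impulse response of a
#' leaky integrator with time constant `mu`.
#'
#' @param t time (timesteps), vectorized.
#' @param mu time constant (> 0).
#' @return kernel values.
#' @export
h_exp <- function(t, mu) {
  stopifnot(mu > 0)
  ifelse(t > 0, exp(-t / mu) / mu, 0)
}

#' Evolve a leaky integrator over a sampled input signal
#'
#' Integrates `mu du/dt = -u + I` with the exponential-Euler update
#' `u <- u exp(-dt/mu) + (1 - exp(-dt/mu)) I`, which is exact for
#' piecewise-constant input and unconditionally stable. In the fine-`dt` limit
#' the result converges to the convolution of the input with the truncated
#' exponential kernel [h_exp()].
#'
#' @param signal numeric vector (or matrix with one column per unit) of input
#'   samples `I`, one per timestep.
#' @param mu membrane time constant (timesteps).
#' @param dt integration step (timesteps).
#' @param u0 initial potential (scalar or one per unit).
#' @return potentials with the same shape as `signal` (value after each step).
#' @export
li_evolve <- function(signal, mu, dt = 1, u0 = 0) {
  stopifnot(mu > 0, dt > 0)
  if (dt >= mu) {
    warning("li_evolve: dt >= mu; the update remains stable but the ",
            "discretization is coarse relative to the time constant")
  }
  a <- exp(-dt / mu)
  if (is.matrix(signal)) {
    u <- matrix(0, nrow(signal), ncol(signal))
    prev <- rep(u0, length.out = ncol(signal))
    for (t in seq_len(nrow(signal))) {
      prev <- a * prev + (1 - a) * signal[t, ]
      u[t, ] <- prev
    }
    u
  } else {
    n <- length(signal)
    # scalar recurrence u_t = a u_{t-1} + (1-a) I_t, closed with filter()
    u <- stats::filter((1 - a) * signal, a, method = "recursive",
                       init = u0)
    as.numeric(u)
  }
}

#' Leaky integrate-and-fire neuron parameters
#'
#' @param mu membrane time constant (timesteps, > 0).
#' @param theta_thr firing threshold (potential units).
#' @param theta_reset reset potential (must be below `theta_thr`).
#' @param mu_r reset time constant (timesteps; 0 = instantaneous reset, the
#'   classical LIF jump condition; > 0 = linearized exponential reset kernel
#'   of the spike response model).
#' @param dt integration step (timesteps).
#' @return an object of class `lif_params`.
#' @export
lif_params <- function(mu = 2, theta_thr = 1, theta_reset = 0, mu_r = 0,
                       dt = 1) {
  stopifnot(mu > 0, mu_r >= 0, dt > 0)
  if (theta_thr <= theta_reset) {
    stop("lif_params: requires theta_thr > theta_reset")
  }
  structure(list(mu = mu, theta_thr = theta_thr, theta_reset = theta_reset,
                 mu_r = mu_r, dt = dt), class = "lif_params")
}

#' Initial state for a population of LIF units
#'
#' @param n number of units.
#' @param u0 initial membrane potential.
#' @return an object of class `lif_state` with fields `u` (potential), `t_f`
#'   (time of last spike, `NA` if none yet), `z` (binary spike output) and
#'   `t` (current time).
#' @export
lif_state <- function(n = 1L, u0 = 0) {
  structure(list(u = rep(u0, n), t_f = rep(NA_real_, n),
                 z = integer(n), t = 0),
            class = "lif_state")
}

#' Advance a LIF population by one integration step
#'
#' Exponential-Euler integration of the membrane equation followed by the
#' Heaviside threshold: units whose potential reaches `theta_thr` emit a spike
#' (`z = 1`), record the spike time and jump to `theta_reset`.
#'
#' @param state a [lif_state()].
#' @param input input current per unit (scalar or length-n).
#' @param params a [lif_params()].
#' @return the updated `lif_state`.
#' @export
lif_step <- function(state, input, params) {
  stopifnot(inherits(state, "lif_state"), inherits(params, "lif_params"))
  a <- exp(-params$dt / params$mu)
  u <- a * state$u + (1 - a) * input
  now <- state$t + params$dt
  fired <- u >= params$theta_thr
  state$z <- as.integer(fired)
  if (any(fired)) {
    if (params$mu_r == 0) {
      u[fired] <- params$theta_reset
    } else {
      # soft reset: subtract the threshold; the remaining relaxation towards
      # theta_reset is carried by the reset kernel in srm_response()
      u[fired] <- u[fired] - params$theta_thr
    }
    state$t_f[fired] <- now
  }
  state$u <- u
  state$t <- now
  state
}

#' Simulate a single LIF unit over a sampled input signal
#'
#' Convenience wrapper around [lif_step()] for one unit driven by a vector of
#' input samples; returns the full membrane trace, the binary spike train and
#' the spike times.
#'
#' @param signal input samples, one per step of length `params$dt`.
#' @param params a [lif_params()].
#' @param u0 initial potential.
#' @return list with `u` (potential after each step), `z` (0/1 spikes),
#'   `spike_times` (in timesteps, end-of-step convention).
#' @export
lif_simulate <- function(signal, params, u0 = 0) {
  n <- length(signal)
  st <- lif_state(1L, u0)
  u <- numeric(n); z <- integer(n)
  for (t in seq_len(n)) {
    st <- lif_step(st, signal[t], params)
    u[t] <- st$u; z[t] <- st$z
  }
  list(u = u, z = z, spike_times = which(z == 1L) * params$dt)
}

#' Spike Response Model closed form for a LIF neuron
#'
#' Evaluates `z(t) = -theta_thr exp(-(t - t_f)/mu_r) + (kappa * I)(t)` with the
#' membrane filter `kappa = h_exp(.; mu)`: the membrane potential as the sum of
#' the subthreshold convolution response and a linearized reset kernel decaying
#' from the last spike time `t_f` with reset time constant `mu_r`. The reset
#' term is causal (zero before `t_f`); with `t_f = -Inf` the response reduces
#' to the pure leaky-integrator output.
#'
#' @param input input samples, one per step of length `params$dt`.
#' @param t_f time of the (single) previous spike, or `-Inf` for none.
#' @param params a [lif_params()] with `mu_r > 0` (or `t_f = -Inf`).
#' @return membrane potential samples at times `dt, 2 dt, ...`.
#' @export
srm_response <- function(input, t_f, params) {
  stopifnot(inherits(params, "lif_params"))
  if (is.finite(t_f) && params$mu_r <= 0) {
    stop("srm_response: mu_r must be positive when a spike time is given")
  }
  u <- li_evolve(input, params$mu, params$dt)
  times <- seq_along(input) * params$dt
  if (is.finite(t_f)) {
    reset <- ifelse(times >= t_f,
                    -params$theta_thr * exp(-(times - t_f) / params$mu_r), 0)
    u <- u + reset
  }
  u
}
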