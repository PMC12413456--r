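#' Spatio-temporal kernel specification
#'
#' Parameters of one separable spatio-temporal receptive field
#' `T(x, t; Sigma, tau, v) = g(x - v t; Sigma) h(t; tau)`: a spatial affine
#' Gaussian moving with image velocity `v`, times a time-causal temporal
#' window of temporal scale `tau`.
#'
#' @param Sigma 2x2 spatial covariance (px^2).
#' @param tau temporal scale (> 0, timestep^2 units; `tau = mu^2`).
#' @param v image velocity (px/timestep, length 2).
#' @return object of class `st_kernel_spec`.
#' @export
st_kernel_spec <- function(Sigma, tau, v = c(0, 0)) {
  stopifnot(is.matrix(Sigma), all(dim(Sigma) == c(2, 2)), tau > 0,
            length(v) == 2)
  structure(list(Sigma = Sigma, tau = tau, v = as.numeric(v)),
            class = "st_kernel_spec")
}

#' Spatio-temporal transformation specification
#'
#' A composed geometric image transformation `x' = A x + u t`,
#' `t' = S_t t`: spatial affine map `A`, Galilean velocity `u` and temporal
#' scaling factor `S_t` (the convention under which the parameter matching
#' rule `v' = (A v + u) / S_t` is exact).
#'
#' @param A invertible 2x2 affine matrix.
#' @param u Galilean velocity (px/timestep, length 2).
#' @param S_t temporal scaling factor (> 0).
#' @return object of class `transform_spec`.
#' @export
transform_spec <- function(A = diag(2), u = c(0, 0), S_t = 1) {
  stopifnot(is.matrix(A), all(dim(A) == c(2, 2)), length(u) == 2, S_t > 0)
  if (abs(det(A)) < 1e-12) stop("transform_spec: 'A' must be invertible")
  structure(list(A = A, u = as.numeric(u), S_t = S_t),
            class = "transform_spec")
}

#' Match receptive-field parameters to a geometric transformation
#'
#' Given receptive-field parameters `(Sigma, tau, v)` in the original domain
#' and a composed transformation `x' = A (x + u t)`, `t' = S_t t`, returns the
#' matched parameters in the transformed domain for which the scale-space
#' representations of the two domains are pointwise equal:
#' `Sigma' = A Sigma A^T`, `tau' = S_t^2 tau`, `v' = (A v + u) / S_t`.
#'
#' @param spec an [st_kernel_spec()].
#' @param xf a [transform_spec()].
#' @return the matched `st_kernel_spec`.
#' @export
match_parameters <- function(spec, xf) {
  stopifnot(inherits(spec, "st_kernel_spec"), inherits(xf, "transform_spec"))
  st_kernel_spec(
    Sigma = transform_covariance(spec$Sigma, xf$A),
    tau = xf$S_t^2 * spec$tau,
    v = as.numeric(xf$A %*% spec$v + xf$u) / xf$S_t)
}

#' Compose two spatio-temporal transformations
#'
#' Returns the single transformation equivalent to applying `xf1` first and
#' `xf2` second. Matching parameters through the composition equals matching
#' through the two transforms in sequence (group consistency).
#'
#' @param xf1,xf2 [transform_spec()] objects (applied in this order).
#' @return the composed `transform_spec`.
#' @export
compose_transforms <- function(xf1, xf2) {
  # convention x' = A x + u t, t' = S_t t (the one under which the velocity
  # matching rule v' = (A v + u) / S_t is exact):
  # x'' = A2 x' + u2 t' = A2 A1 x + (A2 u1 + S1 u2) t,  t'' = S2 S1 t
  transform_spec(
    A = xf2$A %*% xf1$A,
    u = as.numeric(xf2$A %*% xf1$u) + xf1$S_t * xf2$u,
    S_t = xf2$S_t * xf1$S_t)
}

covariance_report <- function(max_abs_deviation, relative_deviation,
                              grid_resolution, matched_params, ...) {
  structure(list(max_abs_deviation = max_abs_deviation,
                 relative_deviation = relative_deviation,
                 grid_resolution = grid_resolution,
                 matched_params = matched_params, ...),
            class = "covariance_report")
}

#' @export
print.covariance_report <- function(x, ...) {
  cat(sprintf("covariance check: relative deviation %.3g (max abs %.3g)\n",
              x$relative_deviation, x$max_abs_deviation))
  if (!is.null(x$control_relative_deviation)) {
    cat(sprintf("  mismatched control arm: relative deviation %.3g\n",
                x$control_relative_deviation))
  }
  invisible(x)
}

default_pulse <- function(t) exp(-(t - 3)^2 / (2 * 0.5^2))

#' Verify temporal scale covariance of the leaky integrator
#'
#' Numerically checks that leaky integration commutes with temporal scaling:
#' the response of a leaky integrator with time constant `mu` to a signal `f`
#' equals, after rescaling time by `S_t`, the response of an integrator with
#' the matched constant `mu' = S_t mu` to the time-rescaled signal. A
#' mismatched control arm (`mu' = mu`) quantifies how specifically the matched
#' constant is required.
#'
#' @param signal function of time on `[0, horizon]` (default: a smooth
#'   Gaussian pulse), or a numeric vector sampled at `fine_dt`.
#' @param S_t temporal scaling factor (> 0).
#' @param mu time constant in the original domain.
#' @param fine_dt integration step for both domains.
#' @param horizon duration of the original-domain signal (timesteps).
#' @return a `covariance_report`; the mismatched arm is reported in
#'   `control_relative_deviation`.
#' @export
verify_temporal_li <- function(signal = default_pulse, S_t = 2, mu = 1,
                               fine_dt = 1e-3, horizon = 10) {
  stopifnot(S_t > 0, mu > 0, fine_dt > 0)
  t1 <- seq(fine_dt, horizon, by = fine_dt)
  f1 <- if (is.function(signal)) signal(t1) else signal
  t2 <- seq(fine_dt, horizon * S_t, by = fine_dt)
  f2 <- if (is.function(signal)) signal(t2 / S_t) else {
    approx(t1, f1, xout = t2 / S_t, rule = 2)$y
  }
  L1 <- li_evolve(f1, mu, fine_dt)
  L2m <- li_evolve(f2, S_t * mu, fine_dt)
  L2c <- li_evolve(f2, mu, fine_dt)
  # compare L1(t) with L2(S_t t) on the original grid
  L2m_at <- approx(t2, L2m, xout = S_t * t1, rule = 2)$y
  L2c_at <- approx(t2, L2c, xout = S_t * t1, rule = 2)$y
  den <- max(abs(L1))
  dev_m <- max(abs(L1 - L2m_at))
  dev_c <- max(abs(L1 - L2c_at))
  covariance_report(
    max_abs_deviation = dev_m,
    relative_deviation = dev_m / den,
    grid_resolution = fine_dt,
    matched_params = list(mu_prime = S_t * mu),
    control_relative_deviation = dev_c / den)
}

default_lif_drive <- function(t) 1.8 + 0.4 * sin(2 * pi * t / 4)

# greedy nearest-time matching of two spike trains; returns index pairs
match_spikes <- function(a, b) {
  if (!length(a) || !length(b)) {
    return(matrix(numeric(0), 0, 2))
  }
  used <- rep(FALSE, length(b))
  out <- matrix(NA_real_, length(a), 2)
  for (i in seq_along(a)) {
    d <- abs(b - a[i]); d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j])) { out[i, ] <- c(i, j); used[j] <- TRUE }
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Verify temporal scale covariance of the leaky integrate-and-fire model
#'
#' Runs a LIF neuron on a signal with constants `(mu, mu_r)` and on the
#' time-rescaled signal with the matched constants `(S_t mu, S_t mu_r)`
#' (threshold unchanged), then checks that the spike counts agree and that the
#' spike times scale as `t'_f = S_t t_f`. A control arm with mismatched
#' constants is reported alongside. The reset is the soft (subtractive)
#' variant, i.e. the `mu_r`-at-grid-resolution limit of the linearized reset
#' kernel, which is itself covariant under time rescaling.
#'
#' @param signal function of time (default: a suprathreshold sinusoidally
#'   modulated drive) or sampled vector.
#' @param S_t temporal scaling factor.
#' @param params [lif_params()] for the original domain; `params$dt` is
#'   ignored in favour of `fine_dt`.
#' @param fine_dt integration step for both domains.
#' @param horizon duration of the original-domain signal.
#' @return a `covariance_report` with `spike_count_equal`,
#'   `max_spike_time_deviation` (timesteps) and control-arm fields.
#' @export
verify_temporal_lif <- function(signal = default_lif_drive, S_t = 2,
                                params = lif_params(mu = 1, mu_r = 0.01,
                                                    dt = 1),
                                fine_dt = 1e-3, horizon = 10) {
  t1 <- seq(fine_dt, horizon, by = fine_dt)
  f1 <- if (is.function(signal)) signal(t1) else signal
  t2 <- seq(fine_dt, horizon * S_t, by = fine_dt)
  f2 <- if (is.function(signal)) signal(t2 / S_t) else {
    approx(t1, f1, xout = t2 / S_t, rule = 2)$y
  }
  p1 <- lif_params(mu = params$mu, theta_thr = params$theta_thr,
                   theta_reset = params$theta_reset,
                   mu_r = max(params$mu_r, fine_dt), dt = fine_dt)
  p2m <- lif_params(mu = S_t * params$mu, theta_thr = params$theta_thr,
                    theta_reset = params$theta_reset,
                    mu_r = S_t * max(params$mu_r, fine_dt), dt = fine_dt)
  p2c <- p1  # mismatched: original constants on the rescaled signal
  r1 <- lif_simulate(f1, p1)
  r2m <- lif_simulate(f2, p2m)
  r2c <- lif_simulate(f2, p2c)
  pairs_m <- match_spikes(S_t * r1$spike_times, r2m$spike_times)
  dev_m <- if (nrow(pairs_m)) {
    max(abs(r2m$spike_times[pairs_m[, 2]] -
              S_t * r1$spike_times[pairs_m[, 1]]))
  } else Inf
  pairs_c <- match_spikes(S_t * r1$spike_times, r2c$spike_times)
  dev_c <- if (nrow(pairs_c)) {
    max(abs(r2c$spike_times[pairs_c[, 2]] -
              S_t * r1$spike_times[pairs_c[, 1]]))
  } else Inf
  covariance_report(
    max_abs_deviation = dev_m,
    relative_deviation = dev_m / (S_t * horizon),
    grid_resolution = fine_dt,
    matched_params = list(mu_prime = S_t * params$mu,
                          mu_r_prime = S_t * max(params$mu_r, fine_dt)),
    spike_count_equal = length(r1$spike_times) == length(r2m$spike_times),
    n_spikes = length(r1$spike_times),
    max_spike_time_deviation = dev_m,
    control_spike_count = length(r2c$spike_times),
    control_max_spike_time_deviation = dev_c,
    control_relative_deviation = dev_c / (S_t * horizon))
}

# band-limited default test image: a handful of Gaussian blobs near the centre
default_test_image <- function(n = 128, seed = 1) {
  set.seed(seed)
  xs <- matrix(0:(n - 1), n, n, byrow = TRUE)
  ys <- matrix(0:(n - 1), n, n)
  img <- matrix(0, n, n)
  for (i in 1:5) {
    cx <- n / 2 + runif(1, -n / 10, n / 10)
    cy <- n / 2 + runif(1, -n / 10, n / 10)
    s <- runif(1, 2, 4)
    img <- img + runif(1, 0.5, 1) * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
  }
  img
}

#' Verify spatial affine covariance of Gaussian smoothing
#'
#' Checks that warping an image by an affine map `A` and smoothing with the
#' matched covariance `A Sigma A^T` equals smoothing with `Sigma` first and
#' warping afterwards, up to bilinear interpolation error. The comparison
#' excludes a boundary margin of three standard deviations of the widest
#' matched kernel axis.
#'
#' @param image numeric matrix (default: a band-limited blob image).
#' @param A invertible 2x2 affine matrix.
#' @param Sigma 2x2 spatial covariance of the original-domain kernel.
#' @return a `covariance_report`.
#' @export
verify_spatial_affine <- function(image = NULL, A = 2 * diag(2),
                                  Sigma = 4 * diag(2)) {
  if (is.null(image)) image <- default_test_image()
  Sigma_p <- transform_covariance(Sigma, A)
  K <- affine_gaussian(Sigma)
  Kp <- affine_gaussian(Sigma_p)
  warp_then_smooth <- conv2d_fft(warp_affine(image, A), Kp)
  smooth_then_warp <- warp_affine(conv2d_fft(image, K), A)
  n <- nrow(image)
  margin <- ceiling(3 * sqrt(max(eigen(Sigma_p, symmetric = TRUE,
                                       only.values = TRUE)$values)))
  margin <- min(margin, floor(n / 2) - 2)
  idx <- (margin + 1):(n - margin)
  a <- warp_then_smooth[idx, idx]; b <- smooth_then_warp[idx, idx]
  den <- max(abs(a), abs(b))
  dev <- max(abs(a - b))
  covariance_report(
    max_abs_deviation = dev,
    relative_deviation = dev / den,
    grid_resolution = n,
    matched_params = list(Sigma_prime = Sigma_p))
}

# analytic Gaussian-blob frame at continuous centre (cx, cy), sd `s`
blob_frame <- function(n, cx, cy, s) {
  xs <- matrix(0:(n - 1), n, n, byrow = TRUE)
  ys <- matrix(0:(n - 1), n, n)
  exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
}

# velocity-adapted leaky-integrator smoothing of a frame stack:
# L(., t) = a * shift(L(., t-1), v dt) + (1 - a) * (g * f_t)
velocity_adapted_response <- function(frames, v, Sigma, mu) {
  K <- affine_gaussian(Sigma)
  a <- exp(-1 / mu)
  L <- NULL
  out <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    sm <- conv2d_fft(frames[[t]], K)
    L <- if (is.null(L)) (1 - a) * sm else {
      a * shift_bilinear(L, v[1], v[2]) + (1 - a) * sm
    }
    out[[t]] <- L
  }
  out
}

#' Verify Galilean covariance of velocity-adapted smoothing
#'
#' For a rigidly translating pattern, velocity-adapted spatio-temporal
#' smoothing with the matched velocity `v' = v + u` applied to the
#' Galilei-warped movie produces a stabilized response whose per-frame peak is
#' constant over time; a mismatched velocity lets the peak decay as the
#' pattern drifts through the receptive field. The report gives the relative
#' peak drift over the post-transient frames for both arms.
#'
#' @param movie list of frames (default: an analytically rendered translating
#'   Gaussian blob).
#' @param u Galilean velocity (px/timestep) applied as `x' = x + u t`.
#' @param spec [st_kernel_spec()]; `spec$v` is the object velocity of the
#'   default movie and the velocity-adaptation of the original domain.
#' @param n_frames,resolution movie geometry for the default movie.
#' @return a `covariance_report`.
#' @export
verify_galilean <- function(movie = NULL, u = c(1.5, 0),
                            spec = st_kernel_spec(9 * diag(2), tau = 4,
                                                  v = c(0.5, 0.25)),
                            n_frames = 36, resolution = 128) {
  mu <- sqrt(spec$tau)
  if (is.null(movie)) {
    n <- resolution
    c0 <- c(n / 2 - n_frames * (spec$v[1] + u[1]) / 2,
            n / 2 - n_frames * (spec$v[2] + u[2]) / 2)
    movie <- lapply(seq_len(n_frames), function(t) {
      blob_frame(n, c0[1] + spec$v[1] * t, c0[2] + spec$v[2] * t, 4)
    })
  }
  # Galilei-warped movie: f'(x, t) = f(x - u t, t)
  warped <- lapply(seq_along(movie), function(t) {
    shift_bilinear(movie[[t]], u[1] * t, u[2] * t)
  })
  v_matched <- spec$v + u
  Lm <- velocity_adapted_response(warped, v_matched, spec$Sigma, mu)
  Lc <- velocity_adapted_response(warped, spec$v, spec$Sigma, mu)
  post <- seq(ceiling(6 * mu), length(movie))
  peaks_m <- vapply(Lm[post], max, numeric(1))
  peaks_c <- vapply(Lc[post], max, numeric(1))
  # reference: the stabilized (matched) steady-state peak; the matched arm
  # should stay at it, the mismatched arm is attenuated by motion smear
  ref <- peaks_m[length(peaks_m)]
  dev <- function(p) max(abs(p - ref)) / ref
  covariance_report(
    max_abs_deviation = max(abs(peaks_m - ref)),
    relative_deviation = dev(peaks_m),
    grid_resolution = nrow(movie[[1]]),
    matched_params = list(v_prime = v_matched),
    control_relative_deviation = dev(peaks_c),
    peaks_matched = peaks_m, peaks_control = peaks_c)
}

#' Joint spatial/temporal scale covariance demonstration
#'
#' Renders squares growing exponentially at different scale velocities (a
#' time-rescaled family of stimuli), applies spatio-temporal receptive fields
#' whose spatial scale tracks the square size and whose time constants are
#' matched to the scale velocities (faster growth gets a proportionally
#' shorter time constant, per the geometric time-constant series), and
#' extracts the response trace at the corresponding moving edge point of each
#' stimulus. In the ideal continuous case the traces are identical after
#' mapping to normalized time; the pairwise correlation and normalized L2
#' distance quantify the residual discretization mismatch.
#'
#' @param velocities initial scale velocities (px/timestep); default a
#'   factor-2 family.
#' @param timesteps number of frames (default 75).
#' @param mus time constants per velocity; default inversely proportional to
#'   velocity, slowest channel at `mu = 8`.
#' @param s0 starting square side (px).
#' @param sigma0 spatial smoothing scale at the starting size (px).
#' @param resolution frame size (px).
#' @return list with per-channel traces on normalized time (`common`), the
#'   pairwise correlation (`cor`) and normalized L2 distance (`l2`) matrices,
#'   and the final square sizes.
#' @export
joint_covariance_demo <- function(velocities = c(0.09, 0.18, 0.36),
                                  timesteps = 75, mus = NULL, s0 = 12,
                                  sigma0 = 3, resolution = 320) {
  nv <- length(velocities)
  if (is.null(mus)) {
    vref <- velocities[velocities > 0]
    mus <- if (length(vref)) 8 * min(vref) / pmax(velocities, min(vref) * 1e-12)
           else rep(8, nv)
    mus[velocities == 0] <- 8
  }
  stopifnot(length(mus) == nv)
  n <- resolution
  cx <- (n - 1) / 2
  wx <- 2 * pi * c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  WX <- matrix(wx, n, n, byrow = TRUE); WY <- matrix(wx, n, n)
  W2 <- WX^2 + WY^2
  xs1 <- 0:(n - 1)
  rates <- velocities / s0
  traces <- matrix(0, timesteps, nv)
  sizes <- matrix(0, timesteps, nv)
  for (i in seq_len(nv)) {
    a <- exp(-1 / mus[i])
    Lx <- Ly <- matrix(0, n, n)
    for (t in seq_len(timesteps)) {
      side <- s0 * exp(rates[i] * t)
      sizes[t, i] <- side
      prof <- pmin(pmax(0.5 + (side / 2 - abs(xs1 - cx)), 0), 1)
      fr <- outer(prof, prof)  # antialiased filled square
      sig <- sigma0 * side / s0
      Ff <- fft(fr)
      Hf <- exp(-sig^2 * W2 / 2)
      gx <- Re(fft(Ff * (1i * WX) * Hf, inverse = TRUE)) / n^2
      gy <- Re(fft(Ff * (1i * WY) * Hf, inverse = TRUE)) / n^2
      # scale-normalized first-order response at the matched spatial scale
      Rsp <- sig * sqrt(gx^2 + gy^2)
      Lx <- a * Lx + (1 - a) * Rsp
      # sample at the corresponding moving edge midpoint (right edge centre)
      traces[t, i] <- bilinear_sample(Lx, cx + side / 2, cx)
    }
  }
  # resample onto common normalized time u = rate * t
  pos <- which(velocities > 0)
  if (length(pos) >= 2) {
    umax <- min(rates[pos] * timesteps)
    ugrid <- seq(umax / 200, umax, length.out = 200)
    common <- sapply(pos, function(i) {
      approx(rates[i] * seq_len(timesteps), traces[, i], xout = ugrid,
             rule = 2)$y
    })
    cmat <- stats::cor(common)
    norms <- sqrt(colSums(common^2))
    l2 <- as.matrix(stats::dist(t(common))) /
      outer(norms, norms, function(a, b) sqrt(a * b))
  } else {
    ugrid <- NULL; common <- NULL; cmat <- NULL; l2 <- NULL
  }
  list(traces = traces, sizes = sizes, mus = mus, velocities = velocities,
       ugrid = ugrid, common = common, cor = cmat, l2 = l2,
       final_sizes = sizes[timesteps, ])
}
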