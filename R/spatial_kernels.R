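#' Specification of one affine Gaussian derivative kernel
#'
#' An affine Gaussian derivative receptive field is parameterized by its
#' orientation, the scale parameters along and orthogonal to that orientation,
#' and the orders of directional differentiation. The induced spatial
#' covariance matrix has eigendirections `orientation` and its orthogonal,
#' with eigenvalues `sigma_par^2` and `sigma_perp^2` (in px^2).
#'
#' @param orientation kernel orientation phi in radians.
#' @param sigma_par spatial scale (px) along the orientation; must satisfy
#'   `sigma_par >= sigma_perp > 0` (eigenvalue ordering convention).
#' @param sigma_perp spatial scale (px) orthogonal to the orientation.
#' @param order_par,order_perp non-negative integer orders of directional
#'   differentiation along / orthogonal to the orientation; at most second
#'   order in total.
#' @param scale dimensionless multiplier `s` on the covariance matrix.
#' @param gamma scale-normalization power (fixed at 1: derivatives of order m
#'   are multiplied by sigma^m so response magnitudes are comparable across
#'   scales).
#' @return an object of class `spatial_kernel_spec`.
#' @export
spatial_kernel_spec <- function(orientation, sigma_par, sigma_perp,
                                order_par = 0L, order_perp = 0L,
                                scale = 1, gamma = 1) {
  if (!is.numeric(sigma_par) || !is.numeric(sigma_perp) ||
      sigma_perp <= 0 || sigma_par <= 0) {
    stop("spatial_kernel_spec: sigma_par and sigma_perp must be positive")
  }
  if (sigma_par < sigma_perp) {
    stop("spatial_kernel_spec: requires sigma_par >= sigma_perp ",
         "(eigenvalue ordering convention)")
  }
  order_par <- as.integer(order_par); order_perp <- as.integer(order_perp)
  if (order_par < 0 || order_perp < 0) {
    stop("spatial_kernel_spec: derivative orders must be non-negative")
  }
  if (order_par + order_perp > 2L) {
    stop("spatial_kernel_spec: derivative orders above 2 are unsupported")
  }
  if (scale <= 0) stop("spatial_kernel_spec: scale must be positive")
  if (gamma != 1) stop("spatial_kernel_spec: only gamma = 1 is supported")
  structure(
    list(orientation = orientation, sigma_par = sigma_par,
         sigma_perp = sigma_perp, order_par = order_par,
         order_perp = order_perp, scale = scale, gamma = gamma),
    class = "spatial_kernel_spec")
}

#' @export
print.spatial_kernel_spec <- function(x, ...) {
  cat(sprintf(
    "affine Gaussian derivative kernel: phi=%.3f rad, sigma=(%.3g, %.3g) px, order=(%d, %d), s=%g\n",
    x$orientation, x$sigma_par, x$sigma_perp, x$order_par, x$order_perp, x$scale))
  invisible(x)
}

#' Spatial covariance matrix induced by a kernel spec
#'
#' Returns `R(phi) diag(sigma_par^2, sigma_perp^2) R(phi)^T`, the symmetric
#' positive-definite covariance matrix whose eigendirections are the kernel
#' orientation and its orthogonal.
#'
#' @param spec a [spatial_kernel_spec()].
#' @return a 2x2 symmetric positive-definite matrix (px^2).
#' @export
covariance_from_spec <- function(spec) {
  stopifnot(inherits(spec, "spatial_kernel_spec"))
  R <- rotation2(spec$orientation)
  R %*% diag(c(spec$sigma_par^2, spec$sigma_perp^2)) %*% t(R)
}

rotation2 <- function(phi) {
  matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
}

#' Transport a spatial covariance matrix through an affine transformation
#'
#' Under the spatial affine transformation `x' = A x`, two Gaussian smoothing
#' operations commute with the warp provided their covariance matrices are
#' coupled as `Sigma' = A Sigma A^T`; this function computes that matched
#' covariance.
#'
#' @param Sigma 2x2 symmetric positive-definite matrix.
#' @param A invertible 2x2 matrix.
#' @return the matched 2x2 covariance `A Sigma A^T`.
#' @export
transform_covariance <- function(Sigma, A) {
  stopifnot(is.matrix(Sigma), all(dim(Sigma) == c(2, 2)),
            is.matrix(A), all(dim(A) == c(2, 2)))
  if (abs(Sigma[1, 2] - Sigma[2, 1]) > 1e-8 * max(abs(Sigma))) {
    stop("transform_covariance: 'Sigma' must be symmetric")
  }
  if (any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("transform_covariance: 'Sigma' must be positive definite")
  }
  if (abs(det(A)) < 1e-12) stop("transform_covariance: 'A' must be invertible")
  S <- A %*% Sigma %*% t(A)
  (S + t(S)) / 2
}

# Sample a (normalized-density) affine Gaussian on an arbitrary centred grid.
# `coords` are the 1-D physical sample positions (px) along both axes;
# x runs along columns, y along rows. Returns the density values (not masses).
gauss2d_grid <- function(Sigma, coords) {
  P <- solve(Sigma)
  X <- matrix(coords, length(coords), length(coords), byrow = TRUE)
  Y <- matrix(coords, length(coords), length(coords))
  q <- P[1, 1] * X^2 + 2 * P[1, 2] * X * Y + P[2, 2] * Y^2
  exp(-q / 2) / (2 * pi * sqrt(det(Sigma)))
}

# Central-difference directional derivative along unit direction (cx, cy),
# grid spacing `delta`, zero padding at the boundary.
dir_central_diff <- function(M, cx, cy, delta) {
  n <- nrow(M)
  padl <- function(M) cbind(matrix(0, n, 1), M[, -n, drop = FALSE])
  padr <- function(M) cbind(M[, -1, drop = FALSE], matrix(0, n, 1))
  padu <- function(M) rbind(matrix(0, 1, n), M[-n, , drop = FALSE])
  padd <- function(M) rbind(M[-1, , drop = FALSE], matrix(0, 1, n))
  dX <- (padr(M) - padl(M)) / (2 * delta)  # d/dx: x increases along columns
  dY <- (padd(M) - padu(M)) / (2 * delta)  # d/dy: y increases along rows
  cx * dX + cy * dY
}

#' Sample a scale-normalized affine Gaussian derivative kernel
#'
#' Samples the continuous kernel
#' `T = sigma_par^m1 sigma_perp^m2 d_phi^m1 d_perp^m2 g(x; s Sigma)` on a
#' high-resolution centred grid spanning the 9x9-px kernel support, realizes
#' the directional derivatives as 3-point central-difference masks applied to
#' the sampled affine Gaussian, and area-downsamples (block sums of per-sample
#' masses) to the target grid. Zeroth-order kernels are renormalized to unit
#' sum; derivative kernels sum to zero by central symmetry of the sampled
#' Gaussian.
#'
#' @param spec a [spatial_kernel_spec()].
#' @param supersample_resolution odd supersampled grid size, a multiple of
#'   `size` and at least 9 (default 81, i.e. 9x supersampling).
#' @param size output grid size in px (default 9, the network kernel size).
#' @return a `size` x `size` numeric kernel matrix.
#' @export
sample_kernel <- function(spec, supersample_resolution = 81L, size = 9L) {
  stopifnot(inherits(spec, "spatial_kernel_spec"))
  N <- as.integer(supersample_resolution)
  if (N %% 2L != 1L || N < size || N %% size != 0L) {
    stop("sample_kernel: supersample_resolution must be an odd multiple of the output size")
  }
  delta <- size / N
  coords <- (seq_len(N) - (N + 1) / 2) * delta
  Sigma <- spec$scale * covariance_from_spec(spec)
  G <- gauss2d_grid(Sigma, coords)
  phi <- spec$orientation
  if (spec$order_par > 0) {
    for (i in seq_len(spec$order_par)) {
      G <- dir_central_diff(G, cos(phi), sin(phi), delta)
    }
  }
  if (spec$order_perp > 0) {
    for (i in seq_len(spec$order_perp)) {
      G <- dir_central_diff(G, -sin(phi), cos(phi), delta)
    }
  }
  s_par <- sqrt(spec$scale) * spec$sigma_par
  s_perp <- sqrt(spec$scale) * spec$sigma_perp
  G <- G * s_par^spec$order_par * s_perp^spec$order_perp  # gamma = 1
  masses <- G * delta^2
  f <- N %/% size
  coarse <- block_sum(masses, f)
  if (spec$order_par + spec$order_perp == 0L) {
    coarse <- coarse / sum(coarse)
  } else {
    # discrete normalization: remove the residual DC component left by grid
    # truncation so derivative kernels integrate to exactly zero
    coarse <- coarse - mean(coarse)
  }
  coarse
}

# Sum over f x f blocks of a (f*m) x (f*m) matrix -> m x m
block_sum <- function(M, f) {
  m <- nrow(M) %/% f
  M2 <- rowsum(M, rep(seq_len(m), each = f))
  out <- t(rowsum(t(M2), rep(seq_len(m), each = f)))
  dimnames(out) <- NULL
  out
}

#' Sample an affine Gaussian smoothing kernel at native image resolution
#'
#' Utility for image-domain smoothing in the covariance verifications: samples
#' `g(x; Sigma)` at unit pixel spacing on a centred odd-sized grid covering
#' `halfwidth` px (default 4 standard deviations of the widest axis), and
#' renormalizes to unit sum.
#'
#' @param Sigma 2x2 symmetric positive-definite covariance (px^2).
#' @param halfwidth kernel half-width in px; default `ceiling(4 * sqrt(max eigenvalue))`.
#' @return odd-sized kernel matrix summing to 1.
#' @export
affine_gaussian <- function(Sigma, halfwidth = NULL) {
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("affine_gaussian: 'Sigma' must be positive definite")
  if (is.null(halfwidth)) halfwidth <- ceiling(4 * sqrt(max(ev)))
  n <- 2L * as.integer(halfwidth) + 1L
  K <- gauss2d_grid(Sigma, seq_len(n) - (n + 1) / 2)
  K / sum(K)
}

#' Build a bank of affine Gaussian derivative kernels
#'
#' Assembles the Cartesian product of orientation, scale, skew and derivative
#' configurations into a bank of discretized 9x9 kernels used as the
#' receptive-field prior of the tracking network. The default configuration
#' (4 orientations x 4 scales x 3 skews x 3 derivative configurations) yields
#' exactly 144 kernels.
#'
#' Orientations are sampled linearly on `[0, pi)`; scales are the octave grid
#' `sigma_par = 1, 2, 4, ... px`; skews are eigenvalue ratios
#' `lambda_perp / lambda_par = 1, 1/2, 1/4, ...` on a geometric grid; the
#' default derivative set holds the two first-order directional derivatives
#' (along and orthogonal to the kernel orientation) and the mixed second
#' order. The zeroth-order (plain smoothing) kernel is available via
#' `derivative_set`.
#'
#' @param orientations number of orientations (default 4).
#' @param scales number of octave-spaced scales (default 4).
#' @param skews number of geometric eigenvalue-ratio values (default 3).
#' @param derivative_set character subset of
#'   `c("par", "perp", "mixed", "zeroth")` selecting derivative orders
#'   (m1, m2) = (1,0), (0,1), (1,1), (0,0).
#' @param sigma_base smallest `sigma_par` (px, default 1).
#' @param supersample_resolution supersampling grid passed to [sample_kernel()].
#' @param size kernel size in px (default 9).
#' @param seed unused placeholder for interface symmetry; the bank is fully
#'   deterministic.
#' @return an object of class `kernel_bank` with elements `kernels`
#'   (size x size x n array) and `specs` (data.frame of kernel parameters).
#' @export
build_bank <- function(orientations = 4L, scales = 4L, skews = 3L,
                       derivative_set = c("par", "perp", "mixed"),
                       sigma_base = 1, supersample_resolution = 81L,
                       size = 9L, seed = NULL) {
  stopifnot(orientations >= 1, scales >= 1, skews >= 1,
            length(derivative_set) >= 1)
  orders <- list(par = c(1L, 0L), perp = c(0L, 1L),
                 mixed = c(1L, 1L), zeroth = c(0L, 0L))
  bad <- setdiff(derivative_set, names(orders))
  if (length(bad)) {
    stop("build_bank: unsupported derivative configuration(s): ",
         paste(bad, collapse = ", "),
         " (orders above 2 are not supported)")
  }
  phis <- seq(0, pi, length.out = orientations + 1)[seq_len(orientations)]
  sigmas <- sigma_base * 2^(seq_len(scales) - 1)
  ratios <- (1 / 2)^(seq_len(skews) - 1)
  grid <- expand.grid(deriv = derivative_set, ratio = ratios,
                      sigma = sigmas, phi = phis,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  kernels <- array(0, dim = c(size, size, n))
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    m <- orders[[grid$deriv[i]]]
    sp <- spatial_kernel_spec(
      orientation = grid$phi[i],
      sigma_par = grid$sigma[i],
      sigma_perp = grid$sigma[i] * sqrt(grid$ratio[i]),
      order_par = m[1], order_perp = m[2])
    kernels[, , i] <- sample_kernel(sp, supersample_resolution, size)
    specs[[i]] <- data.frame(
      orientation = sp$orientation, sigma_par = sp$sigma_par,
      sigma_perp = sp$sigma_perp, order_par = sp$order_par,
      order_perp = sp$order_perp, scale = sp$scale, gamma = sp$gamma)
  }
  structure(list(kernels = kernels, specs = do.call(rbind, specs)),
            class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  d <- dim(x$kernels)
  cat(sprintf("kernel bank: %d affine Gaussian derivative kernels (%dx%d px)\n",
              d[3], d[1], d[2]))
  invisible(x)
}

#' Export a kernel bank as plain-text files
#'
#' Writes `kernels.csv` (one row per kernel, taps in column-major order) and a
#' JSON sidecar `specs.json` describing each kernel's parameters.
#'
#' @param bank a [build_bank()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_kernel_bank <- function(bank, dir) {
  stopifnot(inherits(bank, "kernel_bank"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(bank$kernels)[3]
  flat <- t(apply(bank$kernels, 3, as.vector))
  kpath <- file.path(dir, "kernels.csv")
  spath <- file.path(dir, "specs.json")
  write.csv(as.data.frame(flat), kpath, row.names = FALSE)
  jsonlite::write_json(bank$specs, spath, digits = NA, auto_unbox = TRUE)
  invisible(c(kernels = kpath, specs = spath))
}
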