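#' Derive a stream of child seeds from a master seed
#'
#' Splits one master seed into reproducible per-task child seeds so that, e.g.,
#' every movie in a dataset gets its own independent RNG stream. The scheme is
#' a fixed affine hash kept below 2^31 so the result is always a valid integer
#' seed.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @param stream integer offset separating independent uses of the same master
#'   seed (e.g. dataset generation vs. training).
#' @return integer vector of `n` child seeds.
#' @export
split_seed <- function(seed, n, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  base <- (as.double(seed) %% 2147483647) + 1
  idx <- seq_len(n) + as.double(stream) * 1000003
  as.integer((base * 48271 + idx * 69621) %% 2147483563)
}

# 2D linear convolution via FFT with zero padding; returns an H x W matrix
# aligned with `img` (kernel centre convention: odd-sized kernels, centre tap
# at the middle sample).
conv2d_fft <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  H <- nrow(img); W <- ncol(img)
  ph <- H + kh - 1; pw <- W + kw - 1
  A <- matrix(0, ph, pw); A[1:H, 1:W] <- img
  B <- matrix(0, ph, pw); B[1:kh, 1:kw] <- kernel
  Cf <- fft(fft(A) * fft(B), inverse = TRUE) / (ph * pw)
  out <- Re(Cf)
  r0 <- (kh - 1) / 2; c0 <- (kw - 1) / 2
  out[(r0 + 1):(r0 + H), (c0 + 1):(c0 + W)]
}

# Bilinear sampling of matrix `img` at continuous 0-based pixel coordinates
# (x = column direction, y = row direction), with edge clamping. `x` and `y`
# are equal-length vectors; returns a vector of samples.
bilinear_sample <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x <- pmin(pmax(x, 0), W - 1)
  y <- pmin(pmax(y, 0), H - 1)
  x0 <- pmin(floor(x), W - 2); y0 <- pmin(floor(y), H - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- (y0 + 1) + x0 * H  # column-major index of (y0, x0)
  v00 <- img[i00]; v01 <- img[i00 + H]
  v10 <- img[i00 + 1]; v11 <- img[i00 + 1 + H]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

#' Warp an image by an affine map about the grid centre
#'
#' Computes `out(x') = img(A^{-1}(x' - c) + c)` with bilinear interpolation and
#' edge clamping, where `c` is the centre of the pixel grid (0-based pixel
#' centres, x rightward / y downward). This is the discrete counterpart of the
#' spatial affine transformation `x' = A x` used in the covariance analysis.
#'
#' @param img numeric matrix.
#' @param A invertible 2x2 matrix (acts on (x, y) coordinates).
#' @return warped matrix of the same size.
#' @export
warp_affine <- function(img, A) {
  stopifnot(is.matrix(A), all(dim(A) == c(2, 2)))
  if (abs(det(A)) < 1e-12) stop("warp_affine: 'A' must be invertible")
  H <- nrow(img); W <- ncol(img)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  Ai <- solve(A)
  g <- expand.grid(y = 0:(H - 1), x = 0:(W - 1))
  dx <- g$x - cx; dy <- g$y - cy
  xs <- Ai[1, 1] * dx + Ai[1, 2] * dy + cx
  ys <- Ai[2, 1] * dx + Ai[2, 2] * dy + cy
  matrix(bilinear_sample(img, xs, ys), H, W)
}

# Shift an image by a continuous (dx, dy) offset (positive = rightward/down),
# bilinear with clamping.
shift_bilinear <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  g <- expand.grid(y = 0:(H - 1), x = 0:(W - 1))
  matrix(bilinear_sample(img, g$x - dx, g$y - dy), H, W)
}

# relative L-infinity deviation between two arrays over an optional mask
rel_linf <- function(a, b, mask = NULL) {
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  den <- max(abs(a), abs(b), 1e-300)
  max(abs(a - b)) / den
}
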