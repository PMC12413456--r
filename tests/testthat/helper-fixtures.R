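# shared fixtures, built lazily and memoized across test files
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixtures)) assign(key, fn(), envir = .fixtures)
  get(key, envir = .fixtures)
}

default_bank <- function() memo("default_bank", function() build_bank())

small_bank <- function() memo("small_bank", function() scaled_down_bank())

# small temporal-kind event dataset at 64 px for network/training tests
small_dataset <- function() {
  memo("small_dataset", function() {
    make_dataset("temporal", 24, seed = 420, resolution = 64L,
                 start_size = 12)
  })
}

# analytic 2-D Gaussian blob image (amplitude 1)
gauss_blob <- function(n, cx, cy, s) {
  xs <- matrix(0:(n - 1), n, n, byrow = TRUE)
  ys <- matrix(0:(n - 1), n, n)
  exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
}

rotmat <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

# random symmetric positive-definite 2x2 covariance
random_spd <- function() {
  th <- runif(1, 0, pi)
  l1 <- runif(1, 2, 9); l2 <- runif(1, 1, l1)
  R <- rotmat(th)
  R %*% diag(c(l1, l2)) %*% t(R)
}
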