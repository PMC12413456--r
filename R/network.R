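#' Configuration of the scale-channel tracking network
#'
#' The network has four convolutional blocks. Blocks 1--3 are replicated
#' across `n_scale_channels` parallel temporal scale channels (channel `k`
#' uses time constant `mu_k`); each block is one spatial convolution followed
#' by a temporal activation (leaky integrator + ReLU, leaky integrate-and-fire,
#' or a stateless ReLU). Block 4 merges all channels with a 1x1 convolution
#' into one output map per tracked shape, and a differentiable coordinate
#' transform turns each map into an (x, y) estimate. The coordinate head uses
#' leaky integrators in all variants.
#'
#' @param n_scale_channels number of parallel temporal scale channels.
#' @param kernels_per_block spatial kernels per block (channels of blocks
#'   1--3).
#' @param kernel_size spatial kernel size in px.
#' @param n_output_shapes number of tracked shapes (output maps).
#' @param variant `"LI"`, `"LIF"`, `"ReLU-SF"` or `"ReLU-MF"`.
#' @param init `"rf"` (receptive-field prior) or `"uniform"`.
#' @param mf_frames number of stacked input frames for the multi-frame ReLU
#'   variant.
#' @param use_batchnorm insert per-channel normalization before each temporal
#'   activation (off by default).
#' @param resolution input frame size (px).
#' @param input_channels input channels (2 event polarities).
#' @param strides convolution strides of blocks 1--3.
#' @param mu_min,mu_max endpoints of the logarithmic time-constant interval
#'   (timesteps).
#' @param head_temperature softmax temperature of the coordinate head.
#' @param theta_thr,theta_reset LIF threshold and reset potential.
#' @param surrogate_slope slope of the fast-sigmoid surrogate gradient used
#'   for the LIF Heaviside during training.
#' @return object of class `network_config`.
#' @export
network_config <- function(n_scale_channels = 4L, kernels_per_block = 144L,
                           kernel_size = 9L, n_output_shapes = 3L,
                           variant = c("LI", "LIF", "ReLU-SF", "ReLU-MF"),
                           init = c("rf", "uniform"), mf_frames = 8L,
                           use_batchnorm = FALSE, resolution = 300L,
                           input_channels = 2L, strides = c(2L, 2L, 2L),
                           mu_min = 1, mu_max = 4, head_temperature = 1,
                           theta_thr = 1, theta_reset = 0,
                           surrogate_slope = 10) {
  variant <- match.arg(variant)
  init <- match.arg(init)
  stopifnot(n_scale_channels >= 1, kernels_per_block >= 1,
            kernel_size %% 2 == 1, n_output_shapes >= 1,
            length(strides) == 3, mu_min > 0, mu_max >= mu_min)
  structure(list(n_scale_channels = as.integer(n_scale_channels),
                 kernels_per_block = as.integer(kernels_per_block),
                 kernel_size = as.integer(kernel_size),
                 n_output_shapes = as.integer(n_output_shapes),
                 variant = variant, init = init,
                 mf_frames = as.integer(mf_frames),
                 use_batchnorm = isTRUE(use_batchnorm),
                 resolution = as.integer(resolution),
                 input_channels = as.integer(input_channels),
                 strides = as.integer(strides),
                 mu_min = mu_min, mu_max = mu_max,
                 head_temperature = head_temperature,
                 theta_thr = theta_thr, theta_reset = theta_reset,
                 surrogate_slope = surrogate_slope),
            class = "network_config")
}

#' Scaled-down network configuration
#'
#' A small configuration used for desk-scale training experiments: 64x64
#' input, 2 temporal scale channels, 4 spatial kernels per block and strides
#' (4, 2, 2). The matching kernel bank is [scaled_down_bank()].
#'
#' @param ... overrides passed to [network_config()].
#' @return a `network_config`.
#' @export
scaled_down_config <- function(...) {
  defaults <- list(n_scale_channels = 2L, kernels_per_block = 4L,
                   resolution = 64L, strides = c(8L, 2L, 1L))
  do.call(network_config, modifyList(defaults, list(...)))
}

#' @rdname scaled_down_config
#' @export
scaled_down_bank <- function() {
  build_bank(orientations = 2L, scales = 2L, skews = 1L,
             derivative_set = "par")
}

conv_out <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

uniform_conv_init <- function(k, cin, cout) {
  bound <- sqrt(1 / (cin * k * k))
  array(runif(k * k * cin * cout, -bound, bound), dim = c(k, k, cin, cout))
}

#' Build a scale-channel tracking model
#'
#' Allocates and initializes all parameters of the network described by
#' `config`. With `init = "rf"` blocks 1--2 take their spatial kernels from
#' `bank` and their time constants from `mus` (see [initialize_rf()]); with
#' `init = "uniform"` all spatial weights are uniform random in the same
#' per-layer parameter domain as the RF kernels and the time constants are
#' uniform over `[mu_min, mu_max]`. Blocks 3--4 are uniformly initialized in
#' both schemes, and the block-3 time constant is fixed to the fastest
#' (smallest) time constant of the bank.
#'
#' @param config a [network_config()].
#' @param bank a [build_bank()] result with `kernels_per_block` kernels (only
#'   required for `init = "rf"`, but used to set the uniform domain too).
#' @param mus a `temporal_scale_bank` with `n_scale_channels` time constants
#'   (default: endpoint-pinned grid over `[mu_min, mu_max]`).
#' @param seed RNG seed for the random draws.
#' @return object of class `covrf_model`.
#' @export
build_model <- function(config, bank = NULL, mus = NULL, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  if (is.null(mus)) {
    mus <- time_constant_grid(config$mu_min, config$mu_max,
                              config$n_scale_channels)
  }
  stopifnot(mus$K == config$n_scale_channels)
  K <- config$kernels_per_block
  k <- config$kernel_size
  nch <- config$n_scale_channels
  cin <- if (config$variant == "ReLU-MF") {
    config$input_channels * config$mf_frames
  } else config$input_channels
  set.seed(seed)
  model <- list(config = config, mus_init = mus$mus, seed = seed)
  model$params <- list(
    W1 = lapply(seq_len(nch), function(c) uniform_conv_init(k, cin, K)),
    W2 = lapply(seq_len(nch), function(c) uniform_conv_init(k, K, K)),
    W3 = lapply(seq_len(nch), function(c) uniform_conv_init(k, K, K)),
    W4 = uniform_conv_init(1L, K * nch, config$n_output_shapes),
    mu1 = mus$mus, mu2 = mus$mus)
  model$fixed <- list(mu3 = min(mus$mus), mu_head = min(mus$mus))
  class(model) <- "covrf_model"
  if (config$init == "rf") {
    if (is.null(bank)) stop("build_model: init='rf' requires a kernel bank")
    model <- initialize_rf(model, bank, mus)
  } else {
    if (!is.null(bank)) {
      # uniform white noise in the same parameter domain as the RF kernels
      ref <- initialize_rf(model, bank, mus)
      for (c in seq_len(nch)) {
        r1 <- range(ref$params$W1[[c]]); r2 <- range(ref$params$W2[[c]])
        model$params$W1[[c]][] <- runif(length(model$params$W1[[c]]),
                                        r1[1], r1[2])
        model$params$W2[[c]][] <- runif(length(model$params$W2[[c]]),
                                        r2[1], r2[2])
      }
    }
    model$params$mu1 <- runif(nch, config$mu_min, config$mu_max)
    model$params$mu2 <- runif(nch, config$mu_min, config$mu_max)
  }
  model
}

#' Initialize a model from the receptive-field prior
#'
#' Sets the spatial weights of blocks 1--2 from the kernel bank (block 1
#' assigns kernel `j` to every input slice of output channel `j`; block 2
#' does the same scaled by 1/fan-in so response magnitudes are preserved),
#' sets each scale channel's trainable time constants from `mus`, and fixes
#' the block-3 and coordinate-head time constants to the fastest (smallest)
#' time constant. Blocks 3--4 keep their uniform random weights.
#'
#' @param model a [build_model()] result.
#' @param bank kernel bank with `kernels_per_block` members.
#' @param mus `temporal_scale_bank` with one time constant per scale channel.
#' @return the initialized model.
#' @export
initialize_rf <- function(model, bank, mus) {
  stopifnot(inherits(model, "covrf_model"), inherits(bank, "kernel_bank"))
  cfg <- model$config
  K <- cfg$kernels_per_block
  if (dim(bank$kernels)[3] != K) {
    stop("initialize_rf: bank size (", dim(bank$kernels)[3],
         ") does not match kernels_per_block (", K, ")")
  }
  if (dim(bank$kernels)[1] != cfg$kernel_size) {
    stop("initialize_rf: bank kernel size does not match the model")
  }
  for (c in seq_len(cfg$n_scale_channels)) {
    for (j in seq_len(K)) {
      for (ci in seq_len(dim(model$params$W1[[c]])[3])) {
        model$params$W1[[c]][, , ci, j] <- bank$kernels[, , j]
      }
      for (ci in seq_len(K)) {
        model$params$W2[[c]][, , ci, j] <- bank$kernels[, , j] / K
      }
    }
  }
  model$params$mu1 <- mus$mus
  model$params$mu2 <- mus$mus
  model$fixed$mu3 <- min(mus$mus)
  model$fixed$mu_head <- min(mus$mus)
  model
}

#' @export
print.covrf_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "scale-channel model (%s, %s init): %d channels x %d kernels (%dx%d), %d output shapes, %dpx input\n",
    cfg$variant, cfg$init, cfg$n_scale_channels, cfg$kernels_per_block,
    cfg$kernel_size, cfg$kernel_size, cfg$n_output_shapes, cfg$resolution))
  cat(sprintf("  mu (block1) = %s; mu3 = mu_head = %.3g\n",
              paste(signif(x$params$mu1, 3), collapse = ", "),
              x$fixed$mu_head))
  invisible(x)
}

#' Differentiable coordinate transform of activation maps
#'
#' Converts each activation map into one (x, y) coordinate as the weighted
#' spatial average `sum_p w(p) pos(p)` with a normalized non-negative
#' weighting: either the plain normalization of the (rectified) map
#' (`method = "linear"`, the default for standalone use) or a softmax over
#' the map (`method = "softmax"`, used inside the network head, where strict
#' positivity keeps the transform differentiable for arbitrary activations).
#' Coordinates follow the 0-based pixel-centre convention; an all-zero map
#' falls back to the grid centre and sets the `fallback` attribute.
#'
#' @param maps H x W matrix or H x W x S array of activation maps.
#' @param coords_x,coords_y physical positions of the map columns / rows
#'   (default 0-based pixel indices).
#' @param method weighting scheme.
#' @param temperature softmax temperature.
#' @return S x 2 matrix of (x, y) coordinates with attribute `fallback`
#'   (logical per map).
#' @export
coordinate_transform <- function(maps, coords_x = NULL, coords_y = NULL,
                                 method = c("linear", "softmax"),
                                 temperature = 1) {
  method <- match.arg(method)
  if (is.matrix(maps)) maps <- array(maps, dim = c(dim(maps), 1L))
  H <- dim(maps)[1]; W <- dim(maps)[2]; S <- dim(maps)[3]
  if (is.null(coords_x)) coords_x <- 0:(W - 1)
  if (is.null(coords_y)) coords_y <- 0:(H - 1)
  out <- matrix(NA_real_, S, 2)
  fallback <- logical(S)
  for (s in seq_len(S)) {
    m <- maps[, , s]
    if (any(!is.finite(m))) stop("coordinate_transform: non-finite map")
    if (method == "softmax") {
      m <- exp((m - max(m)) / temperature)
    } else {
      m <- pmax(m, 0)
    }
    tot <- sum(m)
    if (tot <= 0) {
      out[s, ] <- c(mean(coords_x), mean(coords_y))
      fallback[s] <- TRUE
    } else {
      w <- m / tot
      out[s, ] <- c(sum(colSums(w) * coords_x), sum(rowSums(w) * coords_y))
    }
  }
  colnames(out) <- c("x", "y")
  attr(out, "fallback") <- fallback
  out
}

# stack the trailing mf_frames frames as channels (zeros before movie start)
stack_mf_input <- function(x, mf_frames) {
  d <- dim(x)  # (H, W, C, T)
  out <- array(0, dim = c(d[1], d[2], d[3] * mf_frames, d[4]))
  for (f in seq_len(mf_frames)) {
    src <- seq_len(d[4]) - (f - 1L)
    ok <- src >= 1L
    out[, , (f - 1L) * d[3] + seq_len(d[3]), which(ok)] <-
      x[, , , src[ok], drop = FALSE]
  }
  out
}

# instance-style normalization over (H, W, T) per channel; returns the
# normalized array plus the statistics needed for the backward pass
bn_fwd <- function(z) {
  d <- dim(z)  # (H, W, C, T)
  n <- d[1] * d[2] * d[4]
  zc <- aperm(z, c(1, 2, 4, 3)); dim(zc) <- c(n, d[3])
  m <- colMeans(zc)
  v <- colMeans(zc^2) - m^2
  sdv <- sqrt(v + 1e-5)
  zn <- sweep(sweep(zc, 2, m), 2, sdv, "/")
  dim(zn) <- c(d[1], d[2], d[4], d[3])
  list(z = aperm(zn, c(1, 2, 4, 3)), zn = zn, sdv = sdv, dims = d)
}

bn_bwd <- function(cache, gy) {
  d <- cache$dims
  n <- d[1] * d[2] * d[4]
  gc <- aperm(gy, c(1, 2, 4, 3)); dim(gc) <- c(n, d[3])
  zn <- cache$zn; dim(zn) <- c(n, d[3])
  gm <- colMeans(gc)
  gzn <- colMeans(gc * zn)
  gx <- sweep(sweep(gc, 2, gm) - sweep(zn, 2, gzn, "*"), 2, cache$sdv, "/")
  dim(gx) <- c(d[1], d[2], d[4], d[3])
  aperm(gx, c(1, 2, 4, 3))
}

# LIF temporal stage over a (n, T) pre-activation matrix: soft (subtractive)
# reset, binary spike output; returns the cache needed for surrogate BPTT.
lif_stage_fwd <- function(zmat, a, theta) {
  n <- nrow(zmat); T <- ncol(zmat)
  v <- matrix(0, n, T); z <- matrix(0, n, T)
  u <- numeric(n)
  for (t in seq_len(T)) {
    vt <- a * u + (1 - a) * zmat[, t]
    st <- as.numeric(vt >= theta)
    v[, t] <- vt; z[, t] <- st
    u <- vt - theta * st
  }
  list(v = v, z = z)
}

lif_stage_bwd <- function(cache, gout, zmat, a, theta, slope) {
  v <- cache$v
  n <- nrow(v); T <- ncol(v)
  gz <- matrix(0, n, T)
  gu <- numeric(n)
  ga <- 0
  for (t in rev(seq_len(T))) {
    surr <- 1 / (1 + slope * abs(v[, t] - theta))^2
    gv <- gu + gout[, t] * surr  # reset treated as detached
    up <- if (t > 1) v[, t - 1] - theta * cache$z[, t - 1] else numeric(n)
    ga <- ga + sum(gv * (up - zmat[, t]))
    gz[, t] <- (1 - a) * gv
    gu <- a * gv
  }
  list(gz = gz, ga = ga)
}

as_weight_matrix <- function(W) {
  d <- dim(W)
  dim(W) <- c(d[1] * d[2] * d[3], d[4])
  W
}

# (Ho, Wo, Cout, T) array <-> (Ho*Wo*T) x Cout matrix with (oh, ow, t) rows
frames_to_mat <- function(a) {
  d <- dim(a)
  m <- aperm(a, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

mat_to_frames <- function(m, Ho, Wo, T) {
  co <- ncol(m)
  dim(m) <- c(Ho, Wo, T, co)
  aperm(m, c(1, 2, 4, 3))
}

# Forward pass through one movie. x: (H, W, C, T) double array.
# Returns predicted coordinates (T x S x 2) and, if keep = TRUE, the caches
# needed for backpropagation through time. Block 1 uses the event-driven
# sparse convolution (its input is the sparse polarity-event tensor); the
# small deeper blocks use the dense im2col path.
model_forward <- function(model, x, keep = FALSE) {
  cfg <- model$config
  if (cfg$variant == "ReLU-MF") x <- stack_mf_input(x, cfg$mf_frames)
  k <- cfg$kernel_size; pad <- k %/% 2L
  nch <- cfg$n_scale_channels
  T <- dim(x)[4]
  caches <- vector("list", nch)
  r3list <- vector("list", nch)
  for (c in seq_len(nch)) {
    a1 <- exp(-1 / model$params$mu1[c])
    a2 <- exp(-1 / model$params$mu2[c])
    a3 <- exp(-1 / model$fixed$mu3)
    z1 <- conv2d_fwd_sparse(x, model$params$W1[[c]], cfg$strides[1], pad)
    s1 <- temporal_stage_fwd(model, z1, a1, keep)
    z2 <- conv2d_fwd(s1$r, model$params$W2[[c]], cfg$strides[2], pad)
    s2 <- temporal_stage_fwd(model, z2, a2, keep)
    z3 <- conv2d_fwd(s2$r, model$params$W3[[c]], cfg$strides[3], pad)
    s3 <- temporal_stage_fwd(model, z3, a3, keep)
    r3list[[c]] <- s3$r
    if (keep) {
      caches[[c]] <- list(s1 = s1, s2 = s2, s3 = s3, a = c(a1, a2, a3))
    }
  }
  d3 <- dim(r3list[[1]])
  merged <- array(0, dim = c(d3[1], d3[2], d3[3] * nch, T))
  for (c in seq_len(nch)) {
    merged[, , (c - 1L) * d3[3] + seq_len(d3[3]), ] <- r3list[[c]]
  }
  # block 4: 1x1 merge convolution as one matrix product
  merged_mat <- frames_to_mat(merged)
  z4 <- mat_to_frames(merged_mat %*% as_weight_matrix(model$params$W4),
                      d3[1], d3[2], T)
  d4 <- dim(z4)
  ah <- exp(-1 / model$fixed$mu_head)
  z4m <- z4; dim(z4m) <- c(d4[1] * d4[2] * d4[3], T)
  uh <- li_chain_fwd(z4m, ah)
  # coordinate head: softmax-weighted average over the map grid
  S_tot <- prod(cfg$strides)
  gx <- (0:(d4[2] - 1)) * S_tot
  gy <- (0:(d4[1] - 1)) * S_tot
  S <- d4[3]
  coords <- array(NA_real_, dim = c(T, S, 2))
  P <- if (keep) array(0, dim = c(d4[1], d4[2], S, T)) else NULL
  uh_a <- uh; dim(uh_a) <- c(d4[1], d4[2], S, T)
  for (t in seq_len(T)) {
    for (s in seq_len(S)) {
      m <- uh_a[, , s, t]
      e <- exp((m - max(m)) / cfg$head_temperature)
      p <- e / sum(e)
      coords[t, s, 1] <- sum(colSums(p) * gx)
      coords[t, s, 2] <- sum(rowSums(p) * gy)
      if (keep) P[, , s, t] <- p
    }
  }
  out <- list(coords = coords, grid = list(x = gx, y = gy))
  if (keep) {
    out$cache <- list(x = x, caches = caches,
                      merged_mat = merged_mat, uh = uh, z4m = z4m, P = P,
                      d3 = d3, d4 = d4, ah = ah, pad = pad)
  }
  out
}

temporal_stage_fwd <- function(model, z, a, keep) {
  cfg <- model$config
  d <- dim(z)
  bn <- NULL
  if (cfg$use_batchnorm) {
    bn <- bn_fwd(z)
    z <- bn$z
  }
  zm <- z; dim(zm) <- c(prod(d[1:3]), d[4])
  if (cfg$variant == "LI") {
    u <- li_chain_fwd(zm, a)
    r <- pmax(u, 0)
    dim(r) <- d
    list(r = r, u = if (keep) u else NULL, zm = if (keep) zm else NULL,
         bn = bn, kind = "LI")
  } else if (cfg$variant == "LIF") {
    st <- lif_stage_fwd(zm, a, cfg$theta_thr)
    r <- st$z; dim(r) <- d
    list(r = r, lif = if (keep) st else NULL, zm = if (keep) zm else NULL,
         bn = bn, kind = "LIF")
  } else {
    r <- pmax(z, 0)
    list(r = r, zsign = if (keep) (z > 0) else NULL, bn = bn, kind = "ReLU")
  }
}

temporal_stage_bwd <- function(model, stage, gr, a) {
  cfg <- model$config
  d <- dim(gr)
  grm <- gr; dim(grm) <- c(prod(d[1:3]), d[4])
  ga <- 0
  if (stage$kind == "LI") {
    gu <- grm * (stage$u > 0)
    bw <- li_chain_bwd(gu, stage$u, stage$zm, a)
    gz <- bw$gz; ga <- bw$ga
  } else if (stage$kind == "LIF") {
    bw <- lif_stage_bwd(stage$lif, grm, stage$zm, a, cfg$theta_thr,
                        cfg$surrogate_slope)
    gz <- bw$gz; ga <- bw$ga
  } else {
    mask <- stage$zsign
    dim(mask) <- dim(grm)
    gz <- grm * mask
  }
  dim(gz) <- d
  if (!is.null(stage$bn)) gz <- bn_bwd(stage$bn, gz)
  list(gz = gz, ga = ga)
}

# Euclidean tracking loss and its gradient on the predicted coordinates.
# labels: (T x S x 2); returns mean distance in px over frames and shapes.
coord_loss <- function(coords, labels, eps = 1e-6) {
  dxy <- coords - labels
  dist <- sqrt(dxy[, , 1]^2 + dxy[, , 2]^2 + eps)
  g <- array(0, dim = dim(coords))
  n <- length(dist)
  g[, , 1] <- dxy[, , 1] / dist / n
  g[, , 2] <- dxy[, , 2] / dist / n
  list(loss = mean(dist), grad = g)
}

# Full backward pass for one movie; returns gradients for every trainable
# parameter (list mirroring model$params).
model_backward <- function(model, fwd, labels) {
  cfg <- model$config
  cache <- fwd$cache
  d4 <- cache$d4; d3 <- cache$d3
  T <- dim(cache$x)[4]
  nch <- cfg$n_scale_channels
  k <- cfg$kernel_size; pad <- cache$pad
  cl <- coord_loss(fwd$coords, labels)
  gx <- fwd$grid$x; gy <- fwd$grid$y
  guh <- array(0, dim = c(d4[1], d4[2], d4[3], T))
  for (t in seq_len(T)) {
    for (s in seq_len(d4[3])) {
      p <- cache$P[, , s, t]
      xhat <- fwd$coords[t, s, 1]; yhat <- fwd$coords[t, s, 2]
      gxs <- cl$grad[t, s, 1]; gys <- cl$grad[t, s, 2]
      X <- matrix(gx, d4[1], d4[2], byrow = TRUE)
      Y <- matrix(gy, d4[1], d4[2])
      guh[, , s, t] <- p * (gxs * (X - xhat) + gys * (Y - yhat)) /
        cfg$head_temperature
    }
  }
  guhm <- guh; dim(guhm) <- c(d4[1] * d4[2] * d4[3], T)
  hb <- li_chain_bwd(guhm, cache$uh, cache$z4m, cache$ah)
  gz4 <- hb$gz; dim(gz4) <- d4
  gz4mat <- frames_to_mat(gz4)
  W4mat <- as_weight_matrix(model$params$W4)
  gW4 <- crossprod(cache$merged_mat, gz4mat)
  dim(gW4) <- dim(model$params$W4)
  gmerged <- mat_to_frames(tcrossprod(gz4mat, W4mat), d3[1], d3[2], T)
  grads <- list(W1 = vector("list", nch), W2 = vector("list", nch),
                W3 = vector("list", nch), W4 = gW4,
                mu1 = numeric(nch), mu2 = numeric(nch))
  for (c in seq_len(nch)) {
    cc <- cache$caches[[c]]
    gr3 <- gmerged[, , (c - 1L) * d3[3] + seq_len(d3[3]), , drop = FALSE]
    b3 <- temporal_stage_bwd(model, cc$s3, gr3, cc$a[3])
    gW3 <- conv2d_bwd_w(cc$s2$r, b3$gz, cfg$strides[3], pad, k)
    gr2 <- conv2d_bwd_x(b3$gz, model$params$W3[[c]], cfg$strides[3], pad,
                        dim(cc$s2$r)[1], dim(cc$s2$r)[2])
    b2 <- temporal_stage_bwd(model, cc$s2, gr2, cc$a[2])
    gW2 <- conv2d_bwd_w(cc$s1$r, b2$gz, cfg$strides[2], pad, k)
    gr1 <- conv2d_bwd_x(b2$gz, model$params$W2[[c]], cfg$strides[2], pad,
                        dim(cc$s1$r)[1], dim(cc$s1$r)[2])
    b1 <- temporal_stage_bwd(model, cc$s1, gr1, cc$a[1])
    gW1 <- conv2d_bwd_w_sparse(cache$x, b1$gz, cfg$strides[1], pad, k)
    grads$W1[[c]] <- gW1; grads$W2[[c]] <- gW2; grads$W3[[c]] <- gW3
    # d a / d mu = a / mu^2 (dt = 1)
    a1 <- cc$a[1]; a2 <- cc$a[2]
    grads$mu1[c] <- b1$ga * a1 / model$params$mu1[c]^2
    grads$mu2[c] <- b2$ga * a2 / model$params$mu2[c]^2
  }
  list(grads = grads, loss = cl$loss)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are a single self-contained JSON archive holding the
#' configuration, every weight tensor (with its dimensions), the fixed and
#' initial time constants and the build seed, at full double precision.
#'
#' @param model a [build_model()] result.
#' @param path checkpoint path (`.json`).
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   reconstructed `covrf_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "covrf_model"))
  pack <- function(x) {
    if (is.list(x)) lapply(x, pack)
    else list(dim = dim(x), data = as.numeric(x))
  }
  obj <- list(config = unclass(model$config),
              params = pack(model$params),
              fixed = model$fixed,
              mus_init = model$mus_init,
              seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- do.call(network_config, lapply(obj$config, unlist))
  unpack <- function(x) {
    if (is.list(x) && !is.null(x[["data"]])) {
      v <- as.numeric(unlist(x$data))
      d <- unlist(x$dim)
      if (is.null(d)) v else array(v, dim = d)
    } else {
      lapply(x, unpack)
    }
  }
  model <- list(config = cfg,
                params = unpack(obj$params),
                fixed = lapply(obj$fixed, unlist),
                mus_init = unlist(obj$mus_init),
                seed = unlist(obj$seed))
  class(model) <- "covrf_model"
  model
}

#' Predict shape trajectories for one event movie
#'
#' Runs the model forward over a movie and returns the per-frame coordinate
#' predictions and, if labels are present, the mean per-frame L2 tracking
#' error in px.
#'
#' @param model a [build_model()] result.
#' @param movie an `event_movie` (or a raw `(H, W, C, T)` array).
#' @return list with `coords` (T x S x 2) and `loss` (px; `NULL` without
#'   labels).
#' @export
predict_movie <- function(model, movie) {
  x <- if (inherits(movie, "event_movie")) {
    array(as.double(movie$frames), dim = dim(movie$frames))
  } else movie
  fwd <- model_forward(model, x, keep = FALSE)
  loss <- NULL
  if (inherits(movie, "event_movie")) {
    S <- model$config$n_output_shapes
    loss <- coord_loss(fwd$coords,
                       movie$labels[, seq_len(S), , drop = FALSE])$loss
  }
  list(coords = fwd$coords, loss = loss)
}
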