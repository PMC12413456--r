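test_that("coordinate transform computes weighted spatial averages", {
  m <- matrix(0, 300, 300)
  m[21, 11] <- 1  # row 21 = y 20, col 11 = x 10
  out <- coordinate_transform(m)
  expect_equal(out[1, ], c(x = 10, y = 20))
  # uniform map gives the frame centre under the pixel-centre convention
  u <- coordinate_transform(matrix(1, 300, 300))
  expect_equal(u[1, ], c(x = 149.5, y = 149.5))
  # two equal masses average to the midpoint
  m2 <- matrix(0, 30, 30)
  m2[1, 1] <- 1; m2[1, 11] <- 1
  expect_equal(coordinate_transform(m2)[1, ], c(x = 5, y = 0))
  # all-zero map falls back to the centre with a flag
  z <- coordinate_transform(matrix(0, 11, 11))
  expect_equal(z[1, ], c(x = 5, y = 5))
  expect_true(attr(z, "fallback"))
  expect_error(coordinate_transform(matrix(NaN, 3, 3)), "non-finite")
})

test_that("coordinate transform is translation equivariant", {
  set.seed(2)
  base <- matrix(0, 40, 40)
  base[15:20, 12:18] <- runif(42)
  shifted <- matrix(0, 40, 40)
  shifted[(15:20) + 7, (12:18) + 5] <- base[15:20, 12:18]
  c0 <- coordinate_transform(base)
  c1 <- coordinate_transform(shifted)
  expect_equal(c1[1, ] - c0[1, ], c(x = 5, y = 7), tolerance = 1e-12)
  # softmax weighting: equivariant once the activation peak dominates the
  # (shift-invariant) background
  peak <- base; peak[base > 0] <- 14 + peak[base > 0]
  peak_sh <- shifted; peak_sh[shifted > 0] <- 14 + peak_sh[shifted > 0]
  c0s <- coordinate_transform(peak, method = "softmax")
  c1s <- coordinate_transform(peak_sh, method = "softmax")
  expect_equal(c1s[1, ] - c0s[1, ], c(x = 5, y = 7), tolerance = 1e-3)
})

test_that("model construction follows the scale-channel architecture", {
  bank <- small_bank()
  cfg <- scaled_down_config(init = "rf")
  m <- build_model(cfg, bank = bank, seed = 5)
  # block-1 weights equal the bank kernels exactly (every input slice)
  for (j in 1:4) {
    expect_equal(m$params$W1[[1]][, , 1, j], bank$kernels[, , j])
    expect_equal(m$params$W1[[2]][, , 2, j], bank$kernels[, , j])
  }
  # channel time constants from the endpoint-pinned grid; block 3 pinned to
  # the fastest constant
  expect_equal(m$params$mu1, c(1, 4))
  expect_equal(m$fixed$mu3, 1)
  expect_equal(m$fixed$mu_head, 1)
  # bank size mismatch is a configuration error
  expect_error(build_model(network_config(kernels_per_block = 10L,
                                          n_scale_channels = 2L),
                           bank = bank),
               "does not match")
  # uniform init draws in the same per-layer domain as the RF kernels
  mu_ <- build_model(scaled_down_config(init = "uniform"), bank = bank,
                     seed = 5)
  r_rf <- range(m$params$W1[[1]])
  expect_true(all(mu_$params$W1[[1]] >= r_rf[1] &
                    mu_$params$W1[[1]] <= r_rf[2]))
  expect_true(all(mu_$params$mu1 >= 1 & mu_$params$mu1 <= 4))
})

test_that("forward pass produces in-frame coordinates for all variants", {
  bank <- small_bank()
  set.seed(31)
  x <- array(0, c(64, 64, 2, 10))
  x[sample(length(x), 800)] <- 1
  for (variant in c("LI", "LIF", "ReLU-SF", "ReLU-MF")) {
    cfg <- scaled_down_config(variant = variant, init = "rf")
    m <- build_model(cfg, bank = bank, seed = 2)
    fwd <- covrf:::model_forward(m, x)
    expect_equal(dim(fwd$coords), c(10, 3, 2))
    expect_true(all(is.finite(fwd$coords)))
    expect_true(all(fwd$coords >= 0 & fwd$coords < 64))
  }
})

test_that("multi-frame variant consumes stacked frame history", {
  x <- array(seq_len(4 * 4 * 2 * 5), c(4, 4, 2, 5)) * 1.0
  st <- covrf:::stack_mf_input(x, 3L)
  expect_equal(dim(st), c(4, 4, 6, 5))
  # frame t holds frames t, t-1, t-2 in channel blocks; zeros before start
  expect_equal(st[, , 1:2, 3], x[, , , 3])
  expect_equal(st[, , 3:4, 3], x[, , , 2])
  expect_equal(st[, , 5:6, 1], array(0, c(4, 4, 2)))
})

test_that("degenerate single-channel single-kernel model builds and runs", {
  cfg <- network_config(n_scale_channels = 1L, kernels_per_block = 1L,
                        resolution = 32L, strides = c(4L, 2L, 1L),
                        n_output_shapes = 1L, init = "uniform")
  m <- build_model(cfg, seed = 1)
  x <- array(rbinom(32 * 32 * 2 * 5, 1, 0.1), c(32, 32, 2, 5)) * 1.0
  fwd <- covrf:::model_forward(m, x)
  expect_equal(dim(fwd$coords), c(5, 1, 2))
})

test_that("the forward pass is temporally causal", {
  bank <- small_bank()
  m <- build_model(scaled_down_config(init = "rf"), bank = bank, seed = 7)
  set.seed(8)
  x <- array(rbinom(64 * 64 * 2 * 12, 1, 0.02), c(64, 64, 2, 12)) * 1.0
  base <- covrf:::model_forward(m, x)$coords
  # perturbing frames after t must not change outputs up to t
  x2 <- x
  x2[, , , 9:12] <- 1 - x2[, , , 9:12]
  pert <- covrf:::model_forward(m, x2)$coords
  expect_equal(pert[1:8, , ], base[1:8, , ])
  expect_false(isTRUE(all.equal(pert[9:12, , ], base[9:12, , ])))
})

test_that("checkpoints round-trip through the JSON archive", {
  m <- build_model(scaled_down_config(init = "rf"), bank = small_bank(),
                   seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  expect_equal(m2$config$variant, m$config$variant)
  expect_equal(m2$fixed$mu3, m$fixed$mu3)
  set.seed(12)
  x <- array(rbinom(64 * 64 * 2 * 4, 1, 0.02), c(64, 64, 2, 4)) * 1.0
  expect_equal(covrf:::model_forward(m2, x)$coords,
               covrf:::model_forward(m, x)$coords)
})

test_that("optional pre-activation normalization trains without diverging", {
  ds <- small_dataset()
  m <- build_model(scaled_down_config(init = "rf", use_batchnorm = TRUE),
                   bank = small_bank(), seed = 10)
  fit <- train(m, ds, train_config(epochs = 1, batch_size = 8, seed = 10))
  expect_true(all(is.finite(fit$history$train_loss)))
})

test_that("single-frame variants consume one frame per timestep (input contract)", {
  cfg_li <- scaled_down_config(variant = "LI")
  cfg_mf <- scaled_down_config(variant = "ReLU-MF", init = "uniform")
  m_li <- build_model(cfg_li, bank = small_bank(), seed = 1)
  m_mf <- build_model(cfg_mf, bank = NULL, seed = 1)
  expect_equal(dim(m_li$params$W1[[1]])[3], 2)       # 2 polarity channels
  expect_equal(dim(m_mf$params$W1[[1]])[3], 2 * 8)   # 8 stacked frames
})
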