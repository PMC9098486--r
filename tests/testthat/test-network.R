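# Architectural blocks: shape contracts, analytic identities and
# loop-oracle equivalence on tiny instances.

test_that("encoding block preserves spatial size and maps channels", {
  set.seed(21)
  x <- rand_feat(32, 32, 3)
  y <- encoding_block_forward(x, 64L)
  expect_equal(dim(y), c(32L, 32L, 64L))
  expect_error(new_encoding_block(3L, 0L), "positive")
})

test_that("zeroing the residual path leaves the main path", {
  set.seed(22)
  blk <- new_encoding_block(2L, 4L, seed = 3)
  x <- rand_feat(6, 6, 2)
  full <- encoding_block_forward(x, blk)
  blk$params[["enc.res.w"]][] <- 0
  blk$params[["enc.res.b"]][] <- 0
  main_only <- encoding_block_forward(x, blk)
  # residual branch of the zeroed block is BN(ReLU(0)) = 0
  resid <- full - main_only
  blk2 <- new_encoding_block(2L, 4L, seed = 3)
  blk2$params[["enc.c0.w"]][] <- 0; blk2$params[["enc.c0.b"]][] <- 0
  expect_false(all(resid == 0))
  expect_equal(main_only + encoding_block_forward(x, blk2), full,
               tolerance = 1e-12)
})

test_that("encoding block matches a nested-loop convolution oracle", {
  set.seed(23)
  blk <- new_encoding_block(1L, 2L, seed = 9)
  x <- rand_feat(4, 4, 1)
  got <- encoding_block_forward(x, blk)
  p <- blk$params
  m <- oracle_conv_unit(x, p[["enc.c0.w"]], p[["enc.c0.b"]])
  m <- oracle_conv_unit(m, p[["enc.c1.w"]], p[["enc.c1.b"]])
  m <- oracle_conv_unit(m, p[["enc.c2.w"]], p[["enc.c2.b"]])
  r <- oracle_conv_unit(x, p[["enc.res.w"]], p[["enc.res.b"]])
  expect_lt(max(abs(got - (m + r))), 1e-5)
})

test_that("encoder halves resolution per stage and enforces divisibility", {
  model <- new_meanet(network_config(in_channels = 3L), seed = 1)
  st <- encode(model, rand_feat(64, 64, 3))
  expect_equal(dim(st$E1)[1:3], c(64L, 64L, 64L))
  expect_equal(dim(st$E2)[1:3], c(32L, 32L, 128L))
  expect_equal(dim(st$E3)[1:3], c(16L, 16L, 256L))
  expect_equal(dim(st$E4)[1:3], c(8L, 8L, 512L))

  tiny <- new_meanet(tiny_net_config(), seed = 1)
  st8 <- encode(tiny, rand_feat(8, 8, 1))
  expect_equal(dim(st8$E4)[1:2], c(1L, 1L))
  expect_error(encode(tiny, rand_feat(60, 60, 1)), "divisible by 8")
})

test_that("EFE emits the configured attention stack at X1 resolution", {
  set.seed(24)
  A <- efe_forward(rand_feat(64, 64, 64), rand_feat(32, 32, 128))
  expect_equal(dim(A), c(64L, 64L, 16L))
  expect_error(efe_forward(rand_feat(8, 8, 2), rand_feat(5, 5, 2)),
               "half")
})

test_that("zeroed X2 branch reduces EFE to the X1 branch", {
  set.seed(25)
  efe <- new_efe(2L, 3L, n_maps = 4L, seed = 7)
  X1 <- rand_feat(8, 8, 2); X2 <- rand_feat(4, 4, 3)
  full <- efe_forward(X1, X2, efe)
  efe0 <- efe
  efe0$params[["efe.s2.w"]][] <- 0
  efe0$params[["efe.s2.b"]][] <- 0
  only1 <- efe_forward(X1, X2, efe0)
  p <- efe$params
  expect_equal(only1, oracle_conv_unit(X1, p[["efe.s1.w"]],
                                       p[["efe.s1.b"]]),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(full, only1)))
})

test_that("EFE matches a conv + bilinear-upsample loop oracle", {
  set.seed(26)
  efe <- new_efe(1L, 1L, n_maps = 2L, seed = 11)
  X1 <- rand_feat(4, 4, 1); X2 <- rand_feat(2, 2, 1)
  got <- efe_forward(X1, X2, efe)
  p <- efe$params
  want <- oracle_conv_unit(X1, p[["efe.s1.w"]], p[["efe.s1.b"]]) +
    oracle_up2(oracle_conv_unit(X2, p[["efe.s2.w"]], p[["efe.s2.b"]]))
  expect_lt(max(abs(got - want)), 1e-5)
})

test_that("attention aggregation is linear and matches the triple loop", {
  set.seed(27)
  A <- rand_feat(2, 2, 3); X1 <- rand_feat(2, 2, 4)
  expect_equal(mag_aggregate(A, X1), oracle_mag_aggregate(A, X1),
               tolerance = 1e-12)
  ones <- array(1, c(5, 5, 16)); X <- rand_feat(5, 5, 7)
  expect_equal(mag_aggregate(ones, X), 16 * X, tolerance = 1e-12)
  expect_equal(mag_aggregate(array(0, c(5, 5, 16)), X), 0 * X)
  for (ci in 1:5) {
    Nm <- sample(1:4, 1); C <- sample(1:4, 1); H <- sample(2:3, 1)
    Ar <- rand_feat(H, H, Nm); Xr <- rand_feat(H, H, C)
    cc <- runif(1, -2, 2)
    expect_equal(mag_aggregate(cc * Ar, Xr), cc * mag_aggregate(Ar, Xr),
                 tolerance = 1e-12)
    expect_equal(mag_aggregate(Ar, Xr), oracle_mag_aggregate(Ar, Xr),
                 tolerance = 1e-12)
  }
  expect_error(mag_aggregate(rand_feat(3, 3, 2), rand_feat(4, 4, 2)),
               "spatial")
})

test_that("squeeze-and-excitation follows the written order and bounds", {
  set.seed(28)
  U <- rand_feat(3, 3, 4)
  st <- se_state(4L, reduction = 2L, seed = 13)
  got <- se_forward(U, st)
  want <- oracle_se(U, st$W1, st$W2)
  expect_lt(max(abs(got$scaled - want$scaled)), 1e-6)
  expect_equal(got$z, want$z, tolerance = 1e-12)
  expect_true(all(got$s >= 0 & got$s <= 1))

  # constant channels squeeze to the constant
  Uc <- array(rep(c(1.5, -2, 0.25, 7), each = 9), c(3, 3, 4))
  expect_equal(se_forward(Uc, st)$z, c(1.5, -2, 0.25, 7))

  # zero gate weights give s = sigmoid(0) = 0.5 everywhere
  st0 <- list(W1 = 0 * st$W1, W2 = 0 * st$W2)
  z0 <- se_forward(U, st0)
  expect_equal(z0$s, rep(0.5, 4))
  expect_equal(z0$scaled, 0.5 * U, tolerance = 1e-12)
})

test_that("MAG yields a one-channel edge prediction and passes zero through", {
  set.seed(29)
  mag <- new_mag(3L, c_y1 = 3L, se_reduction = 2L, seed = 17)
  A <- rand_feat(8, 8, 4); X1 <- rand_feat(8, 8, 3)
  out <- mag_forward(A, X1, mag)
  expect_equal(dim(out$Y1), c(8L, 8L, 3L))
  expect_equal(dim(out$Y2), c(8L, 8L, 1L))
  z <- mag_forward(A, 0 * X1, mag)   # conv biases are zero-initialised
  expect_true(all(z$Y1 == 0) && all(z$Y2 == 0))
})

test_that("MAG equals the composition of its sub-operation oracles", {
  set.seed(30)
  mag <- new_mag(2L, c_y1 = 2L, se_reduction = 2L, seed = 19)
  A <- rand_feat(4, 4, 3); X1 <- rand_feat(4, 4, 2)
  got <- mag_forward(A, X1, mag)
  p <- mag$params
  U <- oracle_mag_aggregate(A, X1)
  Ut <- oracle_se(U, p[["se.w1.w"]], p[["se.w2.w"]])$scaled
  Y1 <- oracle_conv_unit(Ut, p[["edge.y1.w"]], p[["edge.y1.b"]])
  Y2 <- oracle_conv2d(oracle_conv_unit(Ut, p[["edge.y2a.w"]],
                                       p[["edge.y2a.b"]]),
                      p[["edge.y2.w"]], p[["edge.y2.b"]])
  expect_lt(max(abs(got$Y1 - Y1)), 1e-5)
  expect_lt(max(abs(got$Y2 - Y2)), 1e-5)
})

test_that("decoding block honours its resolution contract and gate range", {
  set.seed(31)
  low <- rand_feat(32, 32, 8); high <- rand_feat(16, 16, 12)
  out <- decoding_block_forward(low, high)
  expect_equal(dim(out), c(32L, 32L, 8L))
  expect_error(decoding_block_forward(low, rand_feat(15, 15, 12)), "half")

  blk <- new_decoding_block(4L, 6L, seed = 23)
  lo <- rand_feat(8, 8, 4)
  b1 <- decoding_block_forward(lo, array(0, c(4, 4, 6)), blk)
  p <- blk$params
  expect_equal(b1, oracle_conv_unit(lo, p[["dec.low.w"]], p[["dec.low.b"]]),
               tolerance = 1e-10)
})

test_that("full forward keeps input resolution, probabilities and determinism", {
  model <- new_meanet(tiny_net_config(), seed = 3)
  set.seed(32)
  for (k in 1:4) {
    H <- 8L * sample(1:4, 1); W <- 8L * sample(1:4, 1)
    out <- meanet_forward(model, rand_feat(H, W, 1))
    expect_equal(dim(out$seg_prob), c(H, W, 1L, 1L))
    expect_equal(dim(out$edge_prob), c(H, W, 1L, 1L))
    expect_true(all(out$seg_prob >= 0 & out$seg_prob <= 1))
    expect_true(all(out$edge_prob >= 0 & out$edge_prob <= 1))
  }
  x <- rand_feat(16, 16, 1)
  expect_identical(meanet_forward(model, x), meanet_forward(model, x))
})

test_that("every trainable parameter receives a nonzero gradient", {
  model <- new_meanet(tiny_net_config(), seed = 5)
  sms <- blob_set(4, size = 16L)
  gr <- meanet_gradients(model, sms, training = TRUE)
  expect_setequal(names(gr$grads), names(model$params))
  for (nm in names(gr$grads))
    expect_gt(max(abs(gr$grads[[nm]])), 0)
})

test_that("ablation switches reach every architecture variant", {
  sms <- blob_set(1, size = 16L)
  variants <- list(
    baseline = tiny_net_config(use_efe = FALSE, use_mag = FALSE),
    efe_only = tiny_net_config(use_efe = TRUE, use_mag = FALSE),
    mag_only = tiny_net_config(use_efe = FALSE, use_mag = TRUE),
    e1 = tiny_net_config(efe_stages = 1L),
    e2e3 = tiny_net_config(efe_stages = c(2L, 3L)),
    all_stages = tiny_net_config(efe_stages = 1:4),
    add_fuse = tiny_net_config(fuse_mode = "add"),
    concat_dec = tiny_net_config(decoder_combine = "concat"))
  for (nm in names(variants)) {
    m <- new_meanet(variants[[nm]], seed = 2)
    out <- meanet_forward(m, sms[[1]]$image)
    expect_equal(dim(out$seg_prob)[1:2], c(16L, 16L))
    if (nm == "baseline") expect_null(out$edge_prob)
    else expect_equal(dim(out$edge_prob)[1:2], c(16L, 16L))
  }
  expect_error(network_config(efe_stages = integer(0)), "non-empty")
})

test_that("checkpoints round-trip and reject mismatched configurations", {
  model <- new_meanet(tiny_net_config(), seed = 7)
  tmp <- tempfile(fileext = ".rds")
  save_checkpoint(model, tmp, extra = list(note = "x"))
  back <- load_checkpoint(tmp, config = model$config)
  x <- rand_feat(16, 16, 1)
  expect_identical(meanet_forward(back, x), meanet_forward(model, x))
  expect_error(load_checkpoint(tmp, config = tiny_net_config(use_mag = FALSE)),
               "does not match")
  expect_error(load_checkpoint(tempfile()), "not found")
})
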