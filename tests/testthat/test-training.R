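# Normalization, padding, pair construction and the training loop.

test_that("quantile normalization obeys its contract", {
  expect_identical(quantile_normalize(matrix(7, 5, 5)), matrix(0, 5, 5))
  v <- matrix(0:99, 10, 10)
  q <- quantile_normalize(v, 0.01, 0.99)
  expect_identical(min(q), 0)
  expect_identical(max(q), 1)
  # sort-based quantile oracle (type-7): q01 = 0.99, q99 = 98.01, so the
  # empirical median pixel (value 50) maps to (50 - 0.99) / (98.01 - 0.99)
  expect_equal(q[v == 50], (50 - 0.99) / (98.01 - 0.99), tolerance = 1e-12)
  expect_equal(q[v == 50], 0.5, tolerance = 0.02)
  # idempotence within tolerance
  q2 <- quantile_normalize(q, 0.01, 0.99)
  expect_lt(max(abs(q2 - q)), 0.03)
  expect_error(quantile_normalize(matrix(NA_real_, 2, 2)),
               class = "t1moco_contract_error")
  expect_error(quantile_normalize(v, 0.5, 0.2),
               class = "t1moco_contract_error")
})

test_that("padding is centred, recorded, invertible, and refuses to crop", {
  x <- matrix(rnorm(63 * 64), 63, 64)
  p <- pad_to_size(x, c(64, 64))
  expect_identical(dim(p), c(64L, 64L))
  # odd leftover goes to the bottom by the tie rule
  expect_identical(attr(p, "pad_offset"), c(0L, 0L))
  expect_identical(p[64, ], rep(0, 64))
  expect_identical(crop_to_original(p), x)
  # border exactly zero outside the recorded window (direct summation)
  y <- matrix(1, 20, 24)
  py <- pad_to_size(y, c(64, 64))
  off <- attr(py, "pad_offset")
  expect_identical(sum(py) - sum(py[off[1] + 1:20, off[2] + 1:24]), 0)
  expect_error(pad_to_size(matrix(0, 65, 64), c(64, 64)),
               class = "t1moco_contract_error")
})

test_that("prepared stacks have zero borders after padding", {
  tm <- make_phantom(seed = 3)
  st <- simulate_irw(tm, noise_sigma = 2, seed = 3)
  x <- prepare_stack(st, pad_size = c(80, 80))
  off <- attr(x, "pad_offset")
  inner <- x[off[1] + 1:64, off[2] + 1:64, ]
  expect_identical(sum(x) - sum(inner), 0)
  expect_gte(min(x), 0)
  expect_lte(max(x), 1)
})

test_that("training pairs honour the round-trip invariant", {
  tm <- make_phantom(seed = 5)
  st <- simulate_irw(tm, noise_sigma = 0, seed = 5)
  # no motion: pair is the identity
  p0 <- make_training_pair(st, amplitude_px = 0, seed = 1)
  expect_identical(p0$deformed$images, st$images)
  expect_identical(max(abs(p0$gt_inverse$fields)), 0)
  # 3 px: warping the deformed frame by its ground-truth inverse recovers
  # the clean frame to interpolation tolerance on interior pixels. The
  # max-abs 2% gate holds on band-limited imagery; the phantom's sharp
  # tissue edges admit only a mean gate (bilinear interpolation error is
  # O(edge step) at an edge crossing, for any deformation pipeline).
  smooth <- array(0, c(64, 64, 7))
  withr::with_seed(21, {
    for (k in 1:7) {
      z <- t1moco:::gauss_smooth(matrix(rnorm(64 * 64), 64, 64), 6)
      smooth[, , k] <- (z - min(z)) * 100
    }
  })
  sst <- irw_stack(smooth, default_ti_schedule())
  ps <- make_training_pair(sst, amplitude_px = 3, seed = 2)
  rngs <- diff(range(sst$images))
  for (k in 1:7) {
    rec <- warp(ps$deformed$images[, , k], ps$gt_inverse$fields[, , , k])
    expect_lt(max(abs(rec - sst$images[, , k])[9:56, 9:56]) / rngs, 0.02)
  }
  p <- make_training_pair(st, amplitude_px = 3, seed = 2)
  rng <- diff(range(st$images))
  for (k in c(1, 4, 7)) {
    rec <- warp(p$deformed$images[, , k], p$gt_inverse$fields[, , , k])
    err <- abs(rec - st$images[, , k])[9:56, 9:56]
    expect_lt(mean(err) / rng, 0.02)
  }
  # mean-removed targets
  expect_true(p$gt_inverse$mean_removed)
  expect_lt(max(abs(apply(p$gt_inverse$fields, c(1, 2, 3), mean))), 1e-6)
  # bit-identical regeneration
  p2 <- make_training_pair(st, amplitude_px = 3, seed = 2)
  expect_identical(p$deformed$images, p2$deformed$images)
  expect_identical(p$gt_inverse$fields, p2$gt_inverse$fields)
})

test_that("early stopping follows the patience arithmetic", {
  # plateaus after epoch 5; patience 3 => stops at epoch 8
  curve <- c(1.0, 0.8, 0.6, 0.5, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4)
  expect_identical(t1moco:::early_stop_epoch(curve, patience = 3), 8L)
  # an improvement below min_delta does not reset the counter
  curve2 <- c(1.0, 0.5, 0.5 - 1e-9, 0.5 - 2e-9, 0.5 - 3e-9)
  expect_identical(t1moco:::early_stop_epoch(curve2, patience = 3), 5L)
  expect_identical(t1moco:::early_stop_epoch(c(3, 2, 1), patience = 3),
                   NA_integer_)
})

test_that("the training loop runs, splits, and seeds reproducibly", {
  stacks <- lapply(1:12, function(i) {
    tm <- make_phantom(size = c(32, 32), centre = c(16, 16), r_inner = 4,
                       r_outer = 8, jitter = 1, seed = i)
    simulate_irw(tm, noise_sigma = 1, seed = i)
  })
  cfg <- train_config(pad_size = c(32, 32), max_epochs = 3,
                      patience_epochs = 5, amplitude_px = 2,
                      smoothness_px = 8, fixed_pairs = TRUE, seed = 7)
  model <- build_network(network_config(base_channels = 8), seed = 7)
  fit <- train(model, stacks, cfg)
  expect_identical(nrow(fit$history), 3L)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(is.finite(fit$history$val_loss)))
  # seeding contract: identical first-epoch losses across two runs
  fit2 <- train(build_network(network_config(base_channels = 8), seed = 7),
                stacks, cfg)
  expect_identical(fit$history$train_loss[1], fit2$history$train_loss[1])
  expect_identical(fit$history$val_loss[1], fit2$history$val_loss[1])
  expect_error(train(model, list(), cfg), class = "t1moco_contract_error")
})
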