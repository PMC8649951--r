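# Displacement-field algebra against closed forms and brute-force oracles.

test_that("zero amplitude yields the zero field; bounds are enforced", {
  u <- generate_random_dvf(c(32, 32), 0, 8, seed = 1)
  expect_identical(u, array(0, c(32, 32, 2)))
  expect_error(generate_random_dvf(c(32, 32), -1, 8),
               class = "t1moco_contract_error")
  expect_error(generate_random_dvf(c(32, 32), 2, 0),
               class = "t1moco_contract_error")
})

test_that("generated fields are topology-preserving and bounded", {
  for (seed in 1:4) {
    u <- generate_random_dvf(c(64, 64), 4, 12, seed = seed)
    mag <- sqrt(u[, , 1]^2 + u[, , 2]^2)
    expect_lte(max(mag), 4 + 1e-12)
    expect_gt(ref_min_jacobian(u), 0)       # independent 2x2 scan
  }
})

test_that("field generation is deterministic per seed", {
  a <- generate_random_dvf(c(48, 48), 3, 10, seed = 5)
  b <- generate_random_dvf(c(48, 48), 3, 10, seed = 5)
  c <- generate_random_dvf(c(48, 48), 3, 10, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("mean removal zeroes the per-pixel frame mean", {
  shp <- c(24, 24)
  # identical fields cancel entirely
  f <- generate_random_dvf(shp, 2, 6, seed = 1)
  s <- remove_mean_displacement(dvf_set(rep(list(f), 7)))
  expect_lt(max(abs(s$fields)), 1e-12)
  expect_true(s$mean_removed)
  # arbitrary fields: direct summation oracle
  fields <- lapply(1:7, function(k) generate_random_dvf(shp, 3, 6, seed = k))
  s2 <- remove_mean_displacement(dvf_set(fields))
  acc <- array(0, c(shp, 2))
  for (k in 1:7) acc <- acc + s2$fields[, , , k]
  expect_lt(max(abs(acc / 7)), 1e-6)
  # idempotence and the zero fixed point
  s3 <- remove_mean_displacement(s2)
  expect_equal(s3$fields, s2$fields, tolerance = 1e-12)
  z <- remove_mean_displacement(dvf_set(array(0, c(shp, 2, 7))))
  expect_identical(max(abs(z$fields)), 0)
  expect_true(z$mean_removed)
})

test_that("warp matches its oracles", {
  set.seed(31)
  img <- matrix(rnorm(32 * 32), 32, 32)
  zero <- array(0, c(32, 32, 2))
  expect_identical(warp(img, zero), img)
  # integer column shift
  sh <- array(0, c(32, 32, 2)); sh[, , 2] <- 3
  expect_equal(warp(img, sh, fill_value = 0),
               cbind(img[, 4:32], matrix(0, 32, 3)))
  # everything out of bounds
  far <- array(0, c(32, 32, 2)); far[, , 1] <- 100
  expect_identical(warp(img, far, fill_value = -5),
                   matrix(-5, 32, 32))
  # random fractional field against the scalar-loop reference
  u <- generate_random_dvf(c(32, 32), 2.5, 6, seed = 2)
  expect_equal(warp(img, u), ref_warp(img, u), tolerance = 1e-12)
  # linearity in the image argument
  img2 <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(warp(2 * img - 3 * img2, u),
               2 * warp(img, u) - 3 * warp(img2, u), tolerance = 1e-10)
  expect_error(warp(img, array(0, c(16, 16, 2))),
               class = "t1moco_contract_error")
})

test_that("composition has the right identity and closed forms", {
  shp <- c(32, 32)
  zero <- array(0, c(shp, 2))
  f <- generate_random_dvf(shp, 2, 8, seed = 3)
  expect_equal(compose(zero, f), f, tolerance = 1e-12)
  expect_equal(compose(f, zero), f, tolerance = 1e-12)
  ca <- array(0, c(shp, 2)); ca[, , 1] <- 1.25
  cb <- array(0, c(shp, 2)); cb[, , 2] <- -0.5
  comp <- compose(ca, cb)
  expect_equal(interior(comp, 4)[, , 1],
               interior(ca + cb, 4)[, , 1], tolerance = 1e-12)
  # double-warp equivalence, sharp version: with an integer-valued inner
  # field both routes perform a single effective interpolation, so they
  # agree to machine precision on any image
  set.seed(7)
  img <- matrix(rnorm(prod(shp)), shp[1], shp[2])
  gi <- array(0, c(shp, 2)); gi[, , 1] <- 2; gi[, , 2] <- -1
  m <- 6
  ins <- function(x) x[(1 + m):(shp[1] - m), (1 + m):(shp[2] - m)]
  expect_equal(ins(warp(warp(img, f), gi)),
               ins(warp(img, compose(f, gi))), tolerance = 1e-12)
  # smooth-field version: double interpolation differs from composed
  # single interpolation by image-curvature terms, so a band-limited test
  # image keeps both routes within the 1e-3 interpolation tolerance
  H <- 64
  sm <- sin(2 * pi * outer(1:H, rep(1, H)) / 128) *
    cos(2 * pi * t(outer(1:H, rep(1, H))) / 128)
  fs <- generate_random_dvf(c(H, H), 2, 12, seed = 31)
  gs <- generate_random_dvf(c(H, H), 1.5, 12, seed = 32)
  insH <- function(x) x[(1 + m):(H - m), (1 + m):(H - m)]
  expect_equal(insH(warp(warp(sm, fs), gs)),
               insH(warp(sm, compose(fs, gs))), tolerance = 1e-3)
})

test_that("inversion satisfies its contracts", {
  shp <- c(48, 48)
  zero <- array(0, c(shp, 2))
  expect_identical(invert(zero), zero)
  # constant translation inverts to its negation (interior)
  cc <- array(0, c(shp, 2)); cc[, , 1] <- 2; cc[, , 2] <- -1
  vi <- invert(cc)
  expect_equal(interior(vi, 5), interior(-cc, 5), tolerance = 1e-6)
  # smooth random field: composition residual oracle
  u <- generate_random_dvf(shp, 3, 10, seed = 4)
  v <- invert(u)
  res <- compose(u, v)
  expect_lt(max(abs(interior(res, 6))), 0.05)
  # invert twice returns near the original
  uu <- invert(v)
  expect_lt(max(abs(interior(uu - u, 8))), 0.1)
})
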