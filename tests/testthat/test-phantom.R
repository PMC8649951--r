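# Phantom geometry and the inversion-recovery signal model.

test_that("degenerate or impossible geometry is rejected", {
  expect_error(make_phantom(r_inner = 0, jitter = 0),
               class = "t1moco_geometry_error")
  expect_error(make_phantom(r_inner = 10, r_outer = 8),
               class = "t1moco_geometry_error")
  expect_error(make_phantom(size = c(64, 64), r_outer = 40),
               class = "t1moco_geometry_error")
  expect_error(make_phantom(size = c(16, 16)),
               class = "t1moco_geometry_error")
})

test_that("myocardial pixel count matches a brute-force rasterization", {
  tm <- make_phantom(size = c(64, 64), centre = c(32, 32),
                     r_inner = 8, r_outer = 14, jitter = 0)
  lab <- phantom_labels()
  count <- 0
  for (i in 1:64) for (j in 1:64) {
    d2 <- (i - 32)^2 + (j - 32)^2
    if (d2 <= 14^2 && d2 > 8^2) count <- count + 1
  }
  expect_identical(sum(tm$labels == lab[["myocardium"]]), as.integer(count))
  expect_identical(sum(tm$labels == lab[["blood_pool"]]),
                   sum(outer(1:64, 1:64,
                             function(i, j) (i - 32)^2 + (j - 32)^2 <= 64)))
})

test_that("myocardium is a closed annulus around the blood pool", {
  tm <- make_phantom(jitter = 2, seed = 9)
  lab <- phantom_labels()
  # flood fill from the blood pool centre over non-myocardium pixels must
  # never reach the image border
  blocked <- tm$labels == lab[["myocardium"]]
  H <- nrow(blocked); W <- ncol(blocked)
  start <- round(tm$geometry$centre)
  seen <- matrix(FALSE, H, W)
  queue <- list(start)
  seen[start[1], start[2]] <- TRUE
  touched_border <- FALSE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- p + d
      if (q[1] < 1 || q[1] > H || q[2] < 1 || q[2] > W) {
        touched_border <- TRUE
      } else if (!seen[q[1], q[2]] && !blocked[q[1], q[2]]) {
        seen[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  expect_false(touched_border)
})

test_that("phantom generation is deterministic per seed", {
  a <- make_phantom(jitter = 2, seed = 7)
  b <- make_phantom(jitter = 2, seed = 7)
  c <- make_phantom(jitter = 2, seed = 8)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$labels, c$labels))
})

test_that("signal model obeys its closed forms", {
  # arbitrary-point oracle: direct scalar evaluation of |A - B exp(-TI/T1)|
  expect_equal(ir_signal(300, 100, 200, 1000),
               abs(100 - 200 * exp(-300 / 1000)))
  # null point: TI = T1 ln 2 with B = 2A
  expect_equal(ir_signal(1000 * log(2), 100, 200, 1000), 0, tolerance = 1e-12)
  # asymptote: TI >= 10 T1 recovers M0 to within 0.01%
  expect_lt(abs(ir_signal(10 * 1600, 100, 200, 1600) - 100) / 100, 1e-4)
})

test_that("simulated stacks approach M0 at long TI for every pixel", {
  tm <- make_phantom(seed = 2)
  tis <- c(100, 300, 800, 1500, 2500, 3600, 17000)  # last >= 10 * max T1
  st <- simulate_irw(tm, tis = tis, noise_sigma = 0)
  truth <- tissue_truth(tm)
  m0 <- truth$m0
  last <- st$images[, , 7]
  nz <- m0 > 0
  expect_true(all(abs(last[nz] - m0[nz]) / m0[nz] < 1e-4))
  expect_true(all(st$images >= 0))
})

test_that("noiseless fit round-trips the phantom T1 (spot sample)", {
  tm <- make_phantom(seed = 4)
  st <- simulate_irw(tm, noise_sigma = 0)
  truth <- tissue_truth(tm)
  tissue <- which(tm$labels > 0)
  pick <- tissue[seq(1, length(tissue), length.out = 50)]
  for (p in pick) {
    f <- fit_t1_pixel(matrix(st$images, ncol = 7)[p, ], st$tis)
    expect_identical(f$status, "ok")
    expect_lt(abs(f$t1_ms - truth$t1_ms[p]) / truth$t1_ms[p], 1e-3)
  }
})

test_that("noisy simulation is bit-reproducible per seed", {
  tm <- make_phantom(seed = 1)
  a <- simulate_irw(tm, noise_sigma = 2, seed = 11)
  b <- simulate_irw(tm, noise_sigma = 2, seed = 11)
  c <- simulate_irw(tm, noise_sigma = 2, seed = 12)
  expect_identical(a$images, b$images)
  expect_false(identical(a$images, c$images))
})

test_that("stack construction enforces its invariants", {
  img <- array(1, c(8, 8, 6))
  expect_error(irw_stack(img, 1:6), class = "t1moco_contract_error")
  img7 <- array(1, c(8, 8, 7))
  expect_error(irw_stack(img7 - 2, 1:7), class = "t1moco_contract_error")
  expect_error(irw_stack(img7, c(1, 1, 2, 3, 4, 5, 6)),
               class = "t1moco_contract_error")
  # shuffled TIs are sorted ascending, frames reordered with them
  tis <- c(800, 100, 4800, 1500, 300, 3600, 2500)
  img_tagged <- array(rep(seq_along(tis), each = 64), c(8, 8, 7))
  st <- irw_stack(img_tagged, tis)
  expect_identical(st$tis, sort(tis))
  expect_equal(as.vector(st$images[1, 1, ]), as.numeric(order(tis)))
})

test_that("TI schedule pre-conditions are checked", {
  tm <- make_phantom(seed = 1)
  expect_error(simulate_irw(tm, tis = c(100, 200, 300)),
               class = "t1moco_contract_error")
  expect_error(simulate_irw(tm, tis = c(-1, 2, 3, 4, 5, 6, 7)),
               class = "t1moco_contract_error")
})
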