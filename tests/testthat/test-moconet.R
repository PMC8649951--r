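# Network construction, forward contracts, the multi-scale loss, and
# gradient correctness.

test_that("configuration invariants are enforced", {
  expect_error(network_config(n_scales = 1), class = "t1moco_config_error")
  expect_error(network_config(kernel_size = 5), class = "t1moco_config_error")
  expect_error(network_config(in_frames = 6), class = "t1moco_config_error")
  expect_error(build_network(list()), class = "t1moco_config_error")
})

test_that("forward pass yields DVF sets at all four scales", {
  m <- build_network(network_config(base_channels = 8), seed = 1)
  x <- array(runif(64 * 64 * 7), c(64, 64, 7, 1))
  out <- t1moco:::forward_net(m, x)
  sizes <- vapply(out$dvfs, function(d) dim(d)[1], 1)
  expect_identical(sizes, c(64, 32, 16, 8))
  expect_true(all(vapply(out$dvfs, function(d) all(is.finite(d)), TRUE)))
  expect_identical(vapply(out$dvfs, function(d) dim(d)[3], 1),
                   rep(14, 4))
})

test_that("building twice with one seed reproduces every parameter", {
  a <- build_network(network_config(base_channels = 8), seed = 3)
  b <- build_network(network_config(base_channels = 8), seed = 3)
  c <- build_network(network_config(base_channels = 8), seed = 4)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})

test_that("indivisible spatial sizes are rejected (padding is caller's job)", {
  m <- build_network(network_config(base_channels = 8), seed = 1)
  x <- array(runif(60 * 60 * 7), c(60, 60, 7))
  expect_error(predict_dvfs(m, x), class = "t1moco_contract_error")
})

test_that("the untrained model is an identity corrector and deterministic", {
  m <- build_network(network_config(base_channels = 8), seed = 2)
  x <- array(runif(32 * 32 * 7), c(32, 32, 7))
  p1 <- predict_dvfs(m, x)
  p2 <- predict_dvfs(m, x)
  expect_identical(p1$fields, p2$fields)
  expect_true(all(is.finite(p1$fields)))
  # zero-initialized heads: initial prediction is the identity deformation
  expect_identical(max(abs(p1$fields)), 0)
})

test_that("multiscale loss matches its closed forms", {
  # hand-computed single-scale 1x1 example: prediction (1,2), target (0,0)
  pred <- array(c(1, 2), c(1, 1, 2))
  gt <- array(0, c(1, 1, 2))
  expect_identical(multiscale_loss(list(pred), gt), 2.5)
  # zero at resampled truth, for every scale
  set.seed(11)
  gtf <- array(rnorm(16 * 16 * 14), c(16, 16, 14))
  preds <- list(gtf)
  g <- gtf
  for (s in 2:3) {
    g <- t1moco:::avgpool2(g) / 2
    preds[[s]] <- g
  }
  expect_identical(multiscale_loss(preds, gtf), 0)
  # nonnegativity and strict increase under single-element perturbation
  loss0 <- multiscale_loss(preds, gtf)
  for (s in 1:3) {
    p2 <- preds
    p2[[s]][1, 1, 1] <- p2[[s]][1, 1, 1] + 0.3
    expect_gt(multiscale_loss(p2, gtf), loss0)
  }
  # scale-count / shape mismatch
  expect_error(multiscale_loss(list(array(0, c(8, 8, 14))), gtf),
               class = "t1moco_contract_error")
})

test_that("analytic gradients match finite differences (fixed flow)", {
  cfg <- network_config(n_scales = 2, base_channels = 8)
  mt <- build_network(cfg, seed = 2)
  # perturb only the finest head: the coarse DVF stays identically zero so
  # the warping layer's sampling positions are constant (the backward pass
  # intentionally does not differentiate through the warp's flow argument)
  withr::with_seed(3, {
    mt$params[["head0_w"]] <- mt$params[["head0_w"]] +
      rnorm(length(mt$params[["head0_w"]]), sd = 0.05)
  })
  xt <- array(runif(8 * 8 * 7 * 2), c(8, 8, 7, 2))
  gt <- array(rnorm(8 * 8 * 14 * 2, sd = 0.5), c(8, 8, 14, 2))
  lossfun <- function(model) {
    o <- t1moco:::forward_net(model, xt, training = TRUE)
    t1moco:::multiscale_loss_grads(o$dvfs, gt)$loss
  }
  o <- t1moco:::forward_net(mt, xt, training = TRUE)
  lg <- t1moco:::multiscale_loss_grads(o$dvfs, gt)
  gr <- t1moco:::backward_net(mt, o$cache, lg$grads)
  eps <- 1e-5
  withr::with_seed(4, {
    for (nm in setdiff(names(mt$params), c("head1_w", "head1_b"))) {
      p <- mt$params[[nm]]
      i <- sample(length(p), 1)
      m2 <- mt; m2$params[[nm]][i] <- p[i] + eps
      m3 <- mt; m3$params[[nm]][i] <- p[i] - eps
      fd <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
      an <- gr[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
    }
  })
})

test_that("training loss on one fixed batch decreases over 50 steps", {
  m <- build_network(network_config(base_channels = 8), seed = 5)
  withr::with_seed(6, {
    x <- array(runif(16 * 16 * 7 * 2), c(16, 16, 7, 2))
    gt <- array(rnorm(16 * 16 * 14 * 2, sd = 0.5), c(16, 16, 14, 2))
  })
  opt <- t1moco:::adam_init(m$params)
  losses <- numeric(50)
  for (it in 1:50) {
    o <- t1moco:::forward_net(m, x, training = TRUE)
    m$buffers <- o$buffers
    lg <- t1moco:::multiscale_loss_grads(o$dvfs, gt)
    losses[it] <- lg$loss
    gr <- t1moco:::backward_net(m, o$cache, lg$grads)
    st <- t1moco:::adam_step(m$params, gr, opt, 0.001)
    m$params <- st$params
    opt <- st$state
  }
  expect_lt(losses[50], losses[1])
  expect_true(all(is.finite(losses)))
})

test_that("a model trained on translations recovers the inverse fields", {
  fit <- toy_translation_model()
  errs <- vapply(1:20, function(i) {
    case <- toy_translation_case(seed = 4000 + i)
    pred <- predict_dvfs(fit$model, case$x)
    epe <- sqrt((pred$fields[, , 1, ] - case$gt$fields[, , 1, ])^2 +
                (pred$fields[, , 2, ] - case$gt$fields[, , 2, ])^2)
    mean(epe[13:52, 13:52, ])
  }, 1)
  expect_lt(mean(errs), 1.0)
})
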