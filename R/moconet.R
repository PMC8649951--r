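# The groupwise multi-scale registration network.
#
# Encoder-decoder over the 7-frame IRW stack. The encoder is Siamese: every
# frame passes through the same 3x3 conv / batch-norm / leaky-ReLU /
# max-pool stack (frames folded into the batch dimension), so encoder
# features stay frame-grouped. The decoder refines a displacement estimate
# coarse-to-fine: at each scale it consumes the transposed-conv-upsampled
# features from the previous (coarser) step, the upsampled DVF estimate,
# and the encoder skip features warped frame-wise by that DVF, and emits a
# residual DVF correction through a zero-initialized 1x1 head (so the
# untrained network is an identity corrector). The finest scale yields the
# 7 full-resolution inverse DVFs.

#' Network configuration
#'
#' @param n_scales Number of scales (>= 2; default 4, i.e. DVF estimates at
#'   1, 1/2, 1/4 and 1/8 resolution).
#' @param base_channels Width parameter; decoder width at the finest scale
#'   (doubles with coarseness, capped at 4x), and per-frame encoder width
#'   `max(2, base_channels / 8)` at the finest level, doubling per level.
#' @param kernel_size Convolution kernel size; fixed at 3.
#' @param leaky_slope Negative slope of the leaky ReLU.
#' @param in_frames Number of input frames; fixed at 7.
#' @param out_channels_per_frame Displacement components per frame (2).
#' @return Object of class `network_config`.
#' @export
network_config <- function(n_scales = 4, base_channels = 16, kernel_size = 3,
                           leaky_slope = 0.1, in_frames = 7,
                           out_channels_per_frame = 2) {
  if (n_scales < 2)
    t1moco_stop("t1moco_config_error", "n_scales must be >= 2")
  if (kernel_size != 3)
    t1moco_stop("t1moco_config_error", "kernel_size is fixed at 3")
  if (in_frames != 7)
    t1moco_stop("t1moco_config_error", "in_frames is fixed at 7")
  if (leaky_slope <= 0)
    t1moco_stop("t1moco_config_error", "leaky_slope must be > 0")
  structure(list(n_scales = as.integer(n_scales),
                 base_channels = as.integer(base_channels),
                 kernel_size = 3L, leaky_slope = leaky_slope,
                 in_frames = 7L,
                 out_channels_per_frame = as.integer(out_channels_per_frame)),
            class = "network_config")
}

# Derived layer widths.
net_arch <- function(config) {
  S <- config$n_scales
  B <- config$base_channels
  pf0 <- max(2L, B %/% 8L)
  pf <- pf0 * 2L^(seq_len(S) - 1L)          # per-frame encoder width, level l
  D <- pmin(B * 2L^(0:(S - 1L)), 4L * B)    # decoder width at scale s
  list(S = S, F = config$in_frames, pf = pf, D = D,
       C = 2L * config$in_frames)           # DVF channels (7 frames x 2)
}

he_init <- function(nrowv, ncolv, fan_in) {
  matrix(rnorm(nrowv * ncolv, sd = sqrt(2 / fan_in)), nrowv, ncolv)
}

#' Build a registration model
#'
#' Allocates and deterministically initializes all parameters (He
#' initialization for convolutions; DVF heads zero-initialized so the
#' initial prediction is the identity deformation).
#'
#' @param config A [network_config()].
#' @param seed Integer seed for parameter initialization.
#' @return Object of class `registration_model` with `config`, `params`
#'   (named list) and `buffers` (batch-norm running statistics).
#' @export
build_network <- function(config = network_config(), seed = 1) {
  if (!inherits(config, "network_config"))
    t1moco_stop("t1moco_config_error", "config must be a network_config")
  a <- net_arch(config)
  S <- a$S; pf <- a$pf; D <- a$D; C <- a$C
  params <- list()
  buffers <- list()
  add_bn <- function(name, ch) {
    params[[paste0(name, "_g")]] <<- rep(1, ch)
    params[[paste0(name, "_b")]] <<- rep(0, ch)
    buffers[[name]] <<- list(mean = rep(0, ch), var = rep(1, ch))
  }
  with_seed(seed, {
    for (l in seq_len(S)) {
      cin <- if (l == 1) 1L else pf[l - 1]
      params[[sprintf("enc%d_c1_w", l)]] <- he_init(9 * cin, pf[l], 9 * cin)
      params[[sprintf("enc%d_c1_b", l)]] <- rep(0, pf[l])
      add_bn(sprintf("enc%d_bn1", l), pf[l])
      params[[sprintf("enc%d_c2_w", l)]] <- he_init(9 * pf[l], pf[l], 9 * pf[l])
      params[[sprintf("enc%d_c2_b", l)]] <- rep(0, pf[l])
      add_bn(sprintf("enc%d_bn2", l), pf[l])
    }
    for (s in (S - 1):0) {
      if (s < S - 1) {
        w <- array(rnorm(D[s + 2] * D[s + 1] * 4, sd = sqrt(2 / D[s + 2])),
                   c(D[s + 2], D[s + 1], 4))
        params[[sprintf("up%d_w", s)]] <- w
        params[[sprintf("up%d_b", s)]] <- rep(0, D[s + 1])
        add_bn(sprintf("up%d_bn", s), D[s + 1])
      }
      cin <- if (s == S - 1) a$F * pf[S] else D[s + 1] + C + a$F * pf[s + 1]
      params[[sprintf("dec%d_c1_w", s)]] <- he_init(9 * cin, D[s + 1], 9 * cin)
      params[[sprintf("dec%d_c1_b", s)]] <- rep(0, D[s + 1])
      add_bn(sprintf("dec%d_bn1", s), D[s + 1])
      params[[sprintf("dec%d_c2_w", s)]] <- he_init(9 * D[s + 1], D[s + 1],
                                                    9 * D[s + 1])
      params[[sprintf("dec%d_c2_b", s)]] <- rep(0, D[s + 1])
      add_bn(sprintf("dec%d_bn2", s), D[s + 1])
      params[[sprintf("head%d_w", s)]] <- matrix(0, D[s + 1], C)
      params[[sprintf("head%d_b", s)]] <- rep(0, C)
    }
  })
  structure(list(config = config, params = params, buffers = buffers),
            class = "registration_model")
}

#' @export
print.registration_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("registration model: %d scales, base %d, %d parameters\n",
              x$config$n_scales, x$config$base_channels, np))
  invisible(x)
}

# Concatenate a list of (H, W, C_i, N) arrays along channels.
cat_channels <- function(parts) {
  d1 <- dim(parts[[1]])
  Ctot <- sum(vapply(parts, function(p) dim(p)[3], 1))
  out <- array(0, c(d1[1], d1[2], Ctot, d1[4]))
  at <- 0
  for (p in parts) {
    cp <- dim(p)[3]
    out[, , (at + 1):(at + cp), ] <- p
    at <- at + cp
  }
  out
}

# Warp frame-grouped features (H, W, F*pf, N) frame-wise by a DVF tensor
# (H, W, 2F, N); frame f's block uses flow channels (2f-1, 2f).
warp_frames <- function(feat, flow, pf, Fn) {
  out <- array(0, dim(feat))
  for (f in seq_len(Fn)) {
    blk <- ((f - 1) * pf + 1):(f * pf)
    out[, , blk, ] <- cpp_warp(feat[, , blk, , drop = FALSE],
                               flow[, , (2 * f - 1):(2 * f), , drop = FALSE],
                               0)
  }
  out
}

warp_frames_backward <- function(g, flow, pf, Fn) {
  out <- array(0, dim(g))
  for (f in seq_len(Fn)) {
    blk <- ((f - 1) * pf + 1):(f * pf)
    out[, , blk, ] <- cpp_warp_backward_img(
      g[, , blk, , drop = FALSE],
      flow[, , (2 * f - 1):(2 * f), , drop = FALSE])
  }
  out
}

# conv3 -> BN -> leaky ReLU block; returns output + cache, updates buffers.
# The backward pass recomputes im2col from the cached input (cheaper than
# holding the column matrices in memory at these sizes).
cbr_forward <- function(x, params, buffers, wname, bnname, slope, training) {
  y <- cpp_conv3(x, params[[paste0(wname, "_w")]], params[[paste0(wname, "_b")]])
  bf <- bn_forward(y, params[[paste0(bnname, "_g")]],
                   params[[paste0(bnname, "_b")]],
                   buffers[[bnname]]$mean, buffers[[bnname]]$var, training)
  lf <- lrelu_forward(bf$y, slope)
  list(y = lf$y,
       cache = list(x = x, bn = bf$cache, fac = lf$fac),
       buffer = list(mean = bf$rmean, var = bf$rvar))
}

cbr_backward <- function(g, cache, params, grads, wname, bnname, slope) {
  g <- lrelu_backward(g, cache, slope)
  bb <- bn_backward(g, cache$bn, params[[paste0(bnname, "_g")]])
  grads[[paste0(bnname, "_g")]] <- (grads[[paste0(bnname, "_g")]] %||% 0) + bb$ggamma
  grads[[paste0(bnname, "_b")]] <- (grads[[paste0(bnname, "_b")]] %||% 0) + bb$gbeta
  cb <- cpp_conv3_backward(cache$x, params[[paste0(wname, "_w")]], bb$gx)
  grads[[paste0(wname, "_w")]] <- (grads[[paste0(wname, "_w")]] %||% 0) + cb$gw
  grads[[paste0(wname, "_b")]] <- (grads[[paste0(wname, "_b")]] %||% 0) + cb$gb
  list(gx = cb$gx, grads = grads)
}

# Full forward pass. x: (H, W, 7, N). Returns per-scale DVF tensors
# (finest first: element s+1 has size H/2^s) plus caches for backward.
forward_net <- function(model, x, training = FALSE) {
  cfg <- model$config
  a <- net_arch(cfg)
  S <- a$S; pf <- a$pf; Fn <- a$F; C <- a$C
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[4]
  if (H %% 2^S != 0 || W %% 2^S != 0)
    t1moco_stop("t1moco_contract_error",
                "spatial size %dx%d not divisible by 2^%d (pad first)", H, W, S)
  slope <- cfg$leaky_slope
  buffers <- model$buffers
  params <- model$params
  enc_cache <- vector("list", S)
  E <- vector("list", S)        # frame-grouped skip features per level
  xs <- x
  dim(xs) <- c(H, W, 1L, Fn * N)
  for (l in seq_len(S)) {
    f1 <- cbr_forward(xs, params, buffers, sprintf("enc%d_c1", l),
                      sprintf("enc%d_bn1", l), slope, training)
    buffers[[sprintf("enc%d_bn1", l)]] <- f1$buffer
    f2 <- cbr_forward(f1$y, params, buffers, sprintf("enc%d_c2", l),
                      sprintf("enc%d_bn2", l), slope, training)
    buffers[[sprintf("enc%d_bn2", l)]] <- f2$buffer
    Eg <- f2$y                              # (h, w, pf, 7N)
    dg <- dim(Eg)
    Egr <- Eg
    dim(Egr) <- c(dg[1], dg[2], pf[l] * Fn, N)   # frame-grouped channels
    E[[l]] <- Egr
    pool <- NULL
    if (l < S) {
      pool <- cpp_maxpool2(Eg)
      xs <- pool$out
    }
    enc_cache[[l]] <- list(c1 = f1$cache, c2 = f2$cache,
                           amax = pool$amax, dims = dg)
  }

  dec_cache <- vector("list", S)
  dvfs <- vector("list", S)
  d2 <- NULL
  for (s in (S - 1):0) {
    if (s == S - 1) {
      xin <- E[[S]]
      up_cache <- NULL; updvf <- NULL
    } else {
      u1 <- tconv2_forward(d2, params[[sprintf("up%d_w", s)]],
                           params[[sprintf("up%d_b", s)]])
      bf <- bn_forward(u1, params[[sprintf("up%d_bn_g", s)]],
                       params[[sprintf("up%d_bn_b", s)]],
                       buffers[[sprintf("up%d_bn", s)]]$mean,
                       buffers[[sprintf("up%d_bn", s)]]$var, training)
      buffers[[sprintf("up%d_bn", s)]] <- list(mean = bf$rmean, var = bf$rvar)
      lf <- lrelu_forward(bf$y, slope)
      updvf <- upsample2(dvfs[[s + 2]]) * 2
      warped <- warp_frames(E[[s + 1]], updvf, pf[s + 1], Fn)
      xin <- cat_channels(list(lf$y, updvf, warped))
      up_cache <- list(x = d2, bn = bf$cache, fac = lf$fac,
                       up_ch = dim(lf$y)[3])
    }
    f1 <- cbr_forward(xin, params, buffers, sprintf("dec%d_c1", s),
                      sprintf("dec%d_bn1", s), slope, training)
    buffers[[sprintf("dec%d_bn1", s)]] <- f1$buffer
    f2 <- cbr_forward(f1$y, params, buffers, sprintf("dec%d_c2", s),
                      sprintf("dec%d_bn2", s), slope, training)
    buffers[[sprintf("dec%d_bn2", s)]] <- f2$buffer
    d2 <- f2$y
    head <- conv1x1_forward(d2, params[[sprintf("head%d_w", s)]],
                            params[[sprintf("head%d_b", s)]])
    dvfs[[s + 1]] <- if (s == S - 1) head else updvf + head
    dec_cache[[s + 1]] <- list(c1 = f1$cache, c2 = f2$cache, d2 = d2,
                               up = up_cache, updvf = updvf)
  }
  list(dvfs = dvfs,
       cache = list(enc = enc_cache, dec = dec_cache, E = E,
                    dims = c(H, W, N)),
       buffers = buffers)
}

# Backward pass; g_dvfs is a list of gradients matching forward()$dvfs.
backward_net <- function(model, cache, g_dvfs) {
  cfg <- model$config
  a <- net_arch(cfg)
  S <- a$S; pf <- a$pf; Fn <- a$F; C <- a$C
  slope <- cfg$leaky_slope
  params <- model$params
  grads <- list()
  gE <- vector("list", S)      # grads on frame-grouped skip features
  g_into_d <- NULL             # grad flowing into coarser scale's d2 via tconv
  g_dvf_acc <- g_dvfs
  for (s in 0:(S - 1)) {
    dc <- cache$dec[[s + 1]]
    gdvf <- g_dvf_acc[[s + 1]]
    hb <- conv1x1_backward(dc$d2, params[[sprintf("head%d_w", s)]], gdvf)
    grads[[sprintf("head%d_w", s)]] <- hb$gw
    grads[[sprintf("head%d_b", s)]] <- hb$gb
    g_d2 <- hb$gx
    if (!is.null(g_into_d)) g_d2 <- g_d2 + g_into_d
    b2 <- cbr_backward(g_d2, dc$c2, params, grads,
                       sprintf("dec%d_c2", s), sprintf("dec%d_bn2", s), slope)
    grads <- b2$grads
    b1 <- cbr_backward(b2$gx, dc$c1, params, grads,
                       sprintf("dec%d_c1", s), sprintf("dec%d_bn1", s), slope)
    grads <- b1$grads
    gxin <- b1$gx
    if (s == S - 1) {
      gE[[S]] <- add_or(gE[[S]], gxin)
      g_into_d <- NULL
    } else {
      upc <- dc$up$up_ch
      g_up <- gxin[, , 1:upc, , drop = FALSE]
      g_updvf_cat <- gxin[, , (upc + 1):(upc + C), , drop = FALSE]
      g_warp <- gxin[, , (upc + C + 1):dim(gxin)[3], , drop = FALSE]
      # skip connection: grad through the (flow-detached) warp
      gE[[s + 1]] <- add_or(gE[[s + 1]],
                            warp_frames_backward(g_warp, dc$updvf,
                                                 pf[s + 1], Fn))
      # DVF estimate: residual path + concat path, back through upsampling
      g_updvf <- gdvf + g_updvf_cat
      g_dvf_acc[[s + 2]] <- g_dvf_acc[[s + 2]] +
        upsample2_backward(g_updvf) * 2
      # upsampled decoder features: leaky ReLU, BN, transposed conv
      g <- lrelu_backward(g_up, dc$up, slope)
      bb <- bn_backward(g, dc$up$bn, params[[sprintf("up%d_bn_g", s)]])
      grads[[sprintf("up%d_bn_g", s)]] <- bb$ggamma
      grads[[sprintf("up%d_bn_b", s)]] <- bb$gbeta
      tb <- tconv2_backward(dc$up$x, params[[sprintf("up%d_w", s)]], bb$gx)
      grads[[sprintf("up%d_w", s)]] <- tb$gw
      grads[[sprintf("up%d_b", s)]] <- tb$gb
      g_into_d <- tb$gx
    }
  }

  g_pool_in <- NULL            # grad on the input of level l+1 (pooled E_l)
  for (l in S:1) {
    ec <- cache$enc[[l]]
    gEl <- gE[[l]]
    dg <- ec$dims              # (h, w, pf, 7N)
    dim(gEl) <- dg             # ungroup frames back into the batch dim
    if (l < S && !is.null(g_pool_in))
      gEl <- gEl + cpp_maxpool2_backward(g_pool_in, ec$amax, dg[1], dg[2])
    b2 <- cbr_backward(gEl, ec$c2, params, grads,
                       sprintf("enc%d_c2", l), sprintf("enc%d_bn2", l), slope)
    grads <- b2$grads
    b1 <- cbr_backward(b2$gx, ec$c1, params, grads,
                       sprintf("enc%d_c1", l), sprintf("enc%d_bn1", l), slope)
    grads <- b1$grads
    g_pool_in <- b1$gx
  }
  grads
}

add_or <- function(a, b) if (is.null(a)) b else a + b

# Convert between dvf_set objects and (H, W, 14[, N]) tensors; channel
# 2(f-1)+c is component c of frame f (a plain reshape of (H, W, 2, 7)).
dvfset_to_tensor <- function(set) {
  f <- set$fields
  dim(f) <- c(dim(f)[1], dim(f)[2], 14L)
  f
}

tensor_to_dvfset <- function(x, mean_removed = FALSE) {
  dim(x) <- c(dim(x)[1], dim(x)[2], 2L, 7L)
  dvf_set(x, mean_removed = mean_removed)
}

#' Predict the 7 inverse DVFs for a prepared IRW stack
#'
#' Inference-mode forward pass (batch-norm running statistics, no
#' stochastic layers): maps a normalized, padded stack to the
#' full-resolution set of 7 inverse displacement fields. Deterministic.
#'
#' @param model A trained (or untrained) `registration_model`.
#' @param irw_stack An [irw_stack] whose spatial size is divisible by
#'   `2^n_scales` (see [prepare_stack()]), or an (H, W, 7) array.
#' @return A [dvf_set] of 7 full-resolution fields.
#' @export
predict_dvfs <- function(model, irw_stack) {
  x <- if (inherits(irw_stack, "irw_stack")) irw_stack$images else irw_stack
  if (length(dim(x)) != 3 || dim(x)[3] != 7)
    t1moco_stop("t1moco_contract_error", "expected an (H, W, 7) stack")
  if (!all(is.finite(x)))
    t1moco_stop("t1moco_contract_error", "stack contains non-finite values")
  dim(x) <- c(dim(x), 1L)
  out <- forward_net(model, x, training = FALSE)
  pred <- out$dvfs[[1]]
  dim(pred) <- dim(pred)[1:3]
  tensor_to_dvfset(pred)
}

#' Multi-scale DVF loss
#'
#' Average over scales of the mean squared error between each scale's
#' predicted fields and the ground truth resampled to that scale
#' (2x2 average pooling per halving, displacement values divided by the
#' downsampling factor so fields stay in units of their own grid).
#'
#' @param per_scale_predictions List of predicted field tensors ordered
#'   finest first; element k has spatial size `full / 2^(k-1)` and an even
#'   number of channels (2 per frame). A single array is treated as a
#'   one-element list.
#' @param gt_dvf_set Ground truth at full resolution: a [dvf_set] or an
#'   (H, W, 2F) array.
#' @return Non-negative scalar; zero iff every prediction equals its
#'   resampled target.
#' @export
multiscale_loss <- function(per_scale_predictions, gt_dvf_set) {
  if (!is.list(per_scale_predictions))
    per_scale_predictions <- list(per_scale_predictions)
  gt <- if (inherits(gt_dvf_set, "dvf_set")) dvfset_to_tensor(gt_dvf_set)
        else gt_dvf_set
  S <- length(per_scale_predictions)
  total <- 0
  gt_s <- gt
  for (s in seq_len(S)) {
    pred <- per_scale_predictions[[s]]
    if (!identical(dim(pred)[1:3], dim(gt_s)[1:3]))
      t1moco_stop("t1moco_contract_error",
                  "prediction at scale %d has size %s, expected %s", s - 1,
                  paste(dim(pred), collapse = "x"),
                  paste(dim(gt_s), collapse = "x"))
    total <- total + mean((pred - gt_s)^2)
    if (s < S) gt_s <- avgpool2(gt_s) / 2
  }
  total / S
}

# Loss + gradients for a training batch. preds: forward_net()$dvfs
# (finest first, (h, w, 14, N)); gt: (H, W, 14, N).
multiscale_loss_grads <- function(preds, gt) {
  S <- length(preds)
  total <- 0
  grads <- vector("list", S)
  gt_s <- gt
  for (s in seq_len(S)) {
    diffv <- preds[[s]] - gt_s
    n <- length(diffv)
    total <- total + mean(diffv^2)
    grads[[s]] <- 2 * diffv / (n * S)
    if (s < S) gt_s <- avgpool2(gt_s) / 2
  }
  list(loss = total / S, grads = grads)
}
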