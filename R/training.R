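# Self-supervised training: synthetic-deformation pair construction,
# intensity normalization and padding, and the supervised loop (Adam,
# reduce-on-plateau scheduler, early stopping on validation loss).

#' Quantile-normalize image intensities to the unit interval
#'
#' Clips at the empirical `q_low`/`q_high` quantiles, then maps the clipped
#' range affinely to \[0, 1\]. Constant images (degenerate range) map to all
#' zeros. Idempotent up to floating tolerance.
#'
#' @param image Numeric matrix or array, finite.
#' @param q_low,q_high Quantile bounds, `0 <= q_low < q_high <= 1`.
#' @return Same shape as `image`, values in \[0, 1\].
#' @export
quantile_normalize <- function(image, q_low = 0.01, q_high = 0.99) {
  if (!all(is.finite(image)))
    t1moco_stop("t1moco_contract_error", "image must be finite")
  if (!(q_low >= 0 && q_low < q_high && q_high <= 1))
    t1moco_stop("t1moco_contract_error", "need 0 <= q_low < q_high <= 1")
  lo <- quantile(image, q_low, names = FALSE)
  hi <- quantile(image, q_high, names = FALSE)
  if (hi <= lo) return(image * 0)
  pmin(pmax((image - lo) / (hi - lo), 0), 1)
}

#' Zero-pad an image or stack to a target size, centred
#'
#' Ties (odd leftover) put the extra row/column at the bottom/right. The
#' placement offset is recorded in attribute `pad_offset` (top-left, 0-based)
#' together with `orig_size`, so [crop_to_original()] restores the input
#' exactly.
#'
#' @param x Matrix (H, W) or array (H, W, C).
#' @param pad_size Integer length-2 target size; must be >= the input size
#'   in both dimensions (no silent cropping).
#' @return Padded object of the same kind, with `pad_offset`/`orig_size`
#'   attributes.
#' @export
pad_to_size <- function(x, pad_size) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  if (H > pad_size[1] || W > pad_size[2])
    t1moco_stop("t1moco_contract_error",
                "input %dx%d exceeds pad size %dx%d", H, W,
                pad_size[1], pad_size[2])
  off <- as.integer(c((pad_size[1] - H) %/% 2, (pad_size[2] - W) %/% 2))
  if (is.matrix(x)) {
    out <- matrix(0, pad_size[1], pad_size[2])
    out[off[1] + seq_len(H), off[2] + seq_len(W)] <- x
  } else {
    out <- array(0, c(pad_size[1], pad_size[2], d[3]))
    out[off[1] + seq_len(H), off[2] + seq_len(W), ] <- x
  }
  attr(out, "pad_offset") <- off
  attr(out, "orig_size") <- c(H, W)
  out
}

#' Undo [pad_to_size()]
#' @param x Output of [pad_to_size()] (attributes intact), or any object
#'   plus explicit `offset`/`orig_size`.
#' @param offset,orig_size Override the recorded placement.
#' @return The original-size object.
#' @export
crop_to_original <- function(x, offset = attr(x, "pad_offset"),
                             orig_size = attr(x, "orig_size")) {
  if (is.null(offset) || is.null(orig_size))
    t1moco_stop("t1moco_contract_error", "no padding record to crop by")
  if (is.matrix(x))
    x[offset[1] + seq_len(orig_size[1]), offset[2] + seq_len(orig_size[2])]
  else
    x[offset[1] + seq_len(orig_size[1]), offset[2] + seq_len(orig_size[2]), ,
      drop = FALSE]
}

#' Normalize and pad an IRW stack for the network
#'
#' Quantile normalization is applied to the whole stack (all 7 frames
#' pooled) so the inversion-recovery intensity ordering between frames is
#' preserved; normalization precedes padding so the padded border is
#' exactly zero.
#'
#' @param stack An [irw_stack].
#' @param pad_size Target spatial size (divisible by `2^n_scales` for the
#'   network); defaults to the stack's own size.
#' @param q_low,q_high Quantile bounds.
#' @return (H, W, 7) array with `pad_offset`/`orig_size` attributes.
#' @export
prepare_stack <- function(stack, pad_size = dim(stack$images)[1:2],
                          q_low = 0.01, q_high = 0.99) {
  x <- quantile_normalize(stack$images, q_low, q_high)
  pad_to_size(x, pad_size)
}

#' Build one synthetic-deformation training pair
#'
#' Draws 7 random topology-preserving DVFs, removes their per-pixel mean
#' (relative motion only), warps each clean frame by its field, and takes
#' the frame-wise numerical inverses (again mean-removed) as the
#' ground-truth correction the network must predict.
#'
#' @param clean_stack A motion-free [irw_stack].
#' @param amplitude_px Maximum displacement of each drawn field (pixels).
#' @param smoothness_px Gaussian smoothness of the drawn fields (pixels).
#' @param seed Integer seed; the pair is bit-reproducible per
#'   (stack, seed).
#' @return List of class `training_pair`: `deformed` ([irw_stack]),
#'   `gt_inverse` ([dvf_set], mean-removed), `applied` ([dvf_set]),
#'   `provenance`.
#' @export
make_training_pair <- function(clean_stack, amplitude_px = 3,
                               smoothness_px = 12, seed = 1) {
  shp <- dim(clean_stack$images)[1:2]
  fields <- vector("list", 7)
  for (k in 1:7)
    fields[[k]] <- generate_random_dvf(shp, amplitude_px, smoothness_px,
                                       seed = derive_seed(seed, 101L, k))
  applied <- remove_mean_displacement(dvf_set(fields))
  images <- clean_stack$images
  deformed <- array(0, dim(images))
  inv <- vector("list", 7)
  for (k in 1:7) {
    u <- applied$fields[, , , k]
    deformed[, , k] <- warp(images[, , k], u, fill_value = 0)
    inv[[k]] <- if (amplitude_px == 0) u else invert(u)
  }
  gt <- remove_mean_displacement(dvf_set(inv))
  structure(list(
    deformed = irw_stack(deformed, clean_stack$tis,
                         pixel_spacing = clean_stack$pixel_spacing,
                         meta = c(clean_stack$meta,
                                  list(deformation_seed = seed))),
    gt_inverse = gt,
    applied = applied,
    provenance = list(seed = seed)), class = "training_pair")
}

#' Training configuration
#'
#' Defaults follow the published regime where stated (Adam, initial
#' learning rate 0.001, mini-batch 4, 10 percent validation split,
#' early-stop patience 50 epochs, reduce-on-plateau scheduler); `pad_size`
#' defaults to a desk-scale 64x64 (the full-scale regime used 384x384) and
#' `max_epochs` bounds desk runs.
#'
#' @param lr_init Initial Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param patience_epochs Early-stop patience (epochs without validation
#'   improvement by at least `min_delta`).
#' @param val_fraction Fraction of stacks held out for validation.
#' @param pad_size Network input size (divisible by `2^n_scales`).
#' @param max_epochs Hard epoch cap for desk-scale runs.
#' @param scheduler Reduce-on-plateau parameters: `factor`, `patience`,
#'   `min_lr`.
#' @param min_delta Minimum validation-loss decrease that counts as an
#'   improvement.
#' @param amplitude_px Deformation amplitude; per-pair amplitudes are drawn
#'   uniformly from (0, amplitude_px\] so aligned stacks stay in
#'   distribution.
#' @param smoothness_px Deformation smoothness.
#' @param fixed_pairs If TRUE, deformations are generated once and reused
#'   every epoch; default resamples fresh deformations per epoch.
#' @param seed Master seed (splits, deformations, shuffling).
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr_init = 0.001, batch_size = 4,
                         patience_epochs = 50, val_fraction = 0.10,
                         pad_size = c(64, 64), max_epochs = 200,
                         scheduler = list(factor = 0.5, patience = 10,
                                          min_lr = 1e-5),
                         min_delta = 1e-6, amplitude_px = 3,
                         smoothness_px = 12, fixed_pairs = FALSE, seed = 1) {
  if (!(val_fraction > 0 && val_fraction < 1))
    t1moco_stop("t1moco_config_error", "val_fraction must be in (0, 1)")
  structure(list(lr_init = lr_init, batch_size = as.integer(batch_size),
                 patience_epochs = as.integer(patience_epochs),
                 val_fraction = val_fraction,
                 pad_size = as.integer(pad_size),
                 max_epochs = as.integer(max_epochs), scheduler = scheduler,
                 min_delta = min_delta, amplitude_px = amplitude_px,
                 smoothness_px = smoothness_px,
                 fixed_pairs = isTRUE(fixed_pairs),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Early-stop rule: stop after `patience` consecutive epochs without an
# improvement of at least `min_delta` over the best value so far.
# Returns the 1-based index of the stopping epoch, or NA if never reached.
early_stop_epoch <- function(val_losses, patience, min_delta = 1e-6) {
  best <- Inf
  since <- 0
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best - min_delta) {
      best <- val_losses[e]
      since <- 0
    } else {
      since <- since + 1
      if (since >= patience) return(e)
    }
  }
  NA_integer_
}

# Build the padded input tensor and padded ground-truth field tensor for
# one training pair.
pair_to_tensors <- function(pair, pad_size) {
  x <- prepare_stack(pair$deformed, pad_size)
  gtt <- dvfset_to_tensor(pair$gt_inverse)
  gt <- pad_to_size(gtt, pad_size)
  list(x = x, gt = gt)
}

draw_amplitude <- function(config, seed) {
  if (config$amplitude_px == 0) return(0)
  with_seed(derive_seed(seed, 7L), runif(1, 0, config$amplitude_px))
}

#' Train a registration model on motion-free stacks
#'
#' Splits the stacks into training and validation (disjoint, stable per
#' seed), builds synthetic-deformation pairs (fresh per epoch unless
#' `fixed_pairs`; validation pairs are always fixed so the validation loss
#' is comparable across epochs), and optimizes the multi-scale DVF loss
#' with Adam, a reduce-on-plateau learning-rate scheduler and early
#' stopping. The returned model carries the parameters of the best
#' validation epoch.
#'
#' @param model A `registration_model` from [build_network()].
#' @param clean_stacks List of motion-free [irw_stack]s (>= 10 at desk
#'   scale, >= 2 in any case).
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return List with `model` (trained) and `history` (data.frame of epoch,
#'   train_loss, val_loss, lr).
#' @export
train <- function(model, clean_stacks, config = train_config(),
                  verbose = FALSE) {
  n <- length(clean_stacks)
  if (n < 2)
    t1moco_stop("t1moco_contract_error", "need at least 2 clean stacks")
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- with_seed(derive_seed(config$seed, 1L), sample(n, n_val))
  train_idx <- setdiff(seq_len(n), val_idx)

  make_pair <- function(i, seed) {
    amp <- draw_amplitude(config, seed)
    pair <- make_training_pair(clean_stacks[[i]], amplitude_px = amp,
                               smoothness_px = config$smoothness_px,
                               seed = seed)
    pair_to_tensors(pair, config$pad_size)
  }
  val_pairs <- lapply(seq_along(val_idx), function(j)
    make_pair(val_idx[j], derive_seed(config$seed, 2L, j)))

  eval_val <- function(model) {
    tot <- 0
    for (vp in val_pairs) {
      x <- array(vp$x, c(dim(vp$x), 1L))
      gt <- array(vp$gt, c(dim(vp$gt), 1L))
      out <- forward_net(model, x, training = FALSE)
      tot <- tot + multiscale_loss_grads(out$dvfs, gt)$loss
    }
    tot / length(val_pairs)
  }

  opt <- adam_init(model$params)
  lr <- config$lr_init
  best_val <- Inf
  best_params <- model$params
  best_buffers <- model$buffers
  since_improve <- 0
  since_lr <- 0
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  fixed_cache <- new.env(parent = emptyenv())

  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, 3L, epoch),
                     sample(train_idx, length(train_idx)))
    epoch_loss <- 0
    n_batches <- 0
    bstarts <- seq(1, length(ord), by = config$batch_size)
    for (b in bstarts) {
      ids <- ord[b:min(b + config$batch_size - 1, length(ord))]
      tensors <- lapply(seq_along(ids), function(k) {
        i <- ids[k]
        pseed <- if (config$fixed_pairs) derive_seed(config$seed, 4L, i)
                 else derive_seed(config$seed, 4L, i, epoch)
        key <- as.character(pseed)
        if (config$fixed_pairs && !is.null(fixed_cache[[key]]))
          return(fixed_cache[[key]])
        tp <- make_pair(i, pseed)
        if (config$fixed_pairs) fixed_cache[[key]] <- tp
        tp
      })
      N <- length(tensors)
      H <- config$pad_size[1]; W <- config$pad_size[2]
      x <- array(0, c(H, W, 7, N))
      gt <- array(0, c(H, W, 14, N))
      for (k in seq_len(N)) {
        x[, , , k] <- tensors[[k]]$x
        gt[, , , k] <- tensors[[k]]$gt
      }
      out <- forward_net(model, x, training = TRUE)
      model$buffers <- out$buffers
      lg <- multiscale_loss_grads(out$dvfs, gt)
      if (!is.finite(lg$loss))
        t1moco_stop("t1moco_training_error",
                    "non-finite loss at epoch %d; training aborted", epoch)
      grads <- backward_net(model, out$cache, lg$grads)
      step <- adam_step(model$params, grads, opt, lr)
      model$params <- step$params
      opt <- step$state
      epoch_loss <- epoch_loss + lg$loss
      n_batches <- n_batches + 1
    }
    vl <- eval_val(model)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = epoch_loss / n_batches,
                                val_loss = vl, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f  lr %.2g",
                      epoch, epoch_loss / n_batches, vl, lr))
    if (vl < best_val - config$min_delta) {
      best_val <- vl
      best_params <- model$params
      best_buffers <- model$buffers
      since_improve <- 0
      since_lr <- 0
    } else {
      since_improve <- since_improve + 1
      since_lr <- since_lr + 1
      if (since_lr >= config$scheduler$patience &&
          lr > config$scheduler$min_lr) {
        lr <- max(lr * config$scheduler$factor, config$scheduler$min_lr)
        since_lr <- 0
      }
      if (since_improve >= config$patience_epochs) break
    }
  }
  model$params <- best_params
  model$buffers <- best_buffers
  list(model = model, history = history)
}

#' Motion-correct an IRW stack with a trained model
#'
#' Normalizes and pads the stack, predicts the 7 inverse DVFs, crops them
#' back to the native grid, and warps the original (un-normalized) frames
#' by their fields.
#'
#' @param stack An [irw_stack].
#' @param model A trained `registration_model`.
#' @return List with `corrected` ([irw_stack]), `dvfs` ([dvf_set], native
#'   grid).
#' @export
correct_stack <- function(stack, model) {
  S <- model$config$n_scales
  d <- dim(stack$images)[1:2]
  pad <- as.integer(ceiling(d / 2^S) * 2^S)
  x <- prepare_stack(stack, pad)
  pred <- predict_dvfs(model, x)
  off <- attr(x, "pad_offset")
  fields <- array(0, c(d, 2, 7))
  corrected <- array(0, dim(stack$images))
  for (k in 1:7) {
    u <- pred$fields[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), , k,
                     drop = FALSE]
    u <- array(u, c(d, 2))
    fields[, , , k] <- u
    corrected[, , k] <- warp(stack$images[, , k], u, fill_value = 0)
  }
  list(corrected = irw_stack(corrected, stack$tis,
                             pixel_spacing = stack$pixel_spacing,
                             meta = c(stack$meta,
                                      list(motion_corrected = TRUE))),
       dvfs = dvf_set(fields))
}
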