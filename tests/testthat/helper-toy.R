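# Toy translation-only training world for the network tests: each frame is
# shifted by a constant (mean-removed) translation of up to +/-3 px, whose
# inverse is its exact negation. Small and closed-form, so it exercises the
# full training machinery without the cost of smooth-field inversion.

toy_translation_case <- function(seed) {
  tm <- make_phantom(jitter = 2, seed = seed)
  st <- simulate_irw(tm, noise_sigma = 1, seed = seed)
  tr <- withr::with_seed(seed, matrix(runif(14, -3, 3), 2, 7))
  tr <- tr - rowMeans(tr)
  fields <- array(0, c(64, 64, 2, 7))
  def <- array(0, c(64, 64, 7))
  for (k in 1:7) {
    u <- array(0, c(64, 64, 2))
    u[, , 1] <- tr[1, k]; u[, , 2] <- tr[2, k]
    fields[, , , k] <- u
    def[, , k] <- warp(st$images[, , k], u, fill_value = 0)
  }
  x <- quantile_normalize(def)
  list(x = x, gt = dvf_set(-fields, mean_removed = TRUE))
}

toy_env <- new.env(parent = emptyenv())

toy_translation_model <- function(n_train = 200, epochs = 12, seed = 99) {
  key <- sprintf("m_%d_%d_%d", n_train, epochs, seed)
  if (!is.null(toy_env[[key]])) return(toy_env[[key]])
  cases <- lapply(seq_len(n_train), function(i)
    toy_translation_case(seed = 10000 + i))
  m <- build_network(network_config(base_channels = 8), seed = seed)
  opt <- t1moco:::adam_init(m$params)
  losses <- numeric(0)
  for (e in seq_len(epochs)) {
    ord <- withr::with_seed(seed + e, sample(n_train))
    for (b in seq(1, n_train, by = 4)) {
      ids <- ord[b:min(b + 3, n_train)]
      N <- length(ids)
      x <- array(0, c(64, 64, 7, N))
      gt <- array(0, c(64, 64, 14, N))
      for (k in seq_len(N)) {
        x[, , , k] <- cases[[ids[k]]]$x
        gt[, , , k] <- t1moco:::dvfset_to_tensor(cases[[ids[k]]]$gt)
      }
      o <- t1moco:::forward_net(m, x, training = TRUE)
      m$buffers <- o$buffers
      lg <- t1moco:::multiscale_loss_grads(o$dvfs, gt)
      gr <- t1moco:::backward_net(m, o$cache, lg$grads)
      st <- t1moco:::adam_step(m$params, gr, opt, 0.002)
      m$params <- st$params
      opt <- st$state
      losses <- c(losses, lg$loss)
    }
  }
  out <- list(model = m, losses = losses)
  toy_env[[key]] <- out
  out
}
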