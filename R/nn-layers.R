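# Layer primitives for the registration network. All activations are
# (H, W, C, N) double arrays; forward functions return caches consumed by
# the matching backward functions. Internal.

lrelu_forward <- function(x, slope) {
  fac <- slope + (1 - slope) * (x > 0)
  list(y = x * fac, fac = fac)
}

lrelu_backward <- function(g, cache, slope) {
  g * cache$fac
}

# Batch normalization over dims (H, W, N) per channel.
bn_forward <- function(x, gamma, beta, rmean, rvar, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)    # (HWN) x C
  n <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    v <- colMeans(xc^2)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v * n / max(1, n - 1)
  } else {
    mu <- rmean
    v <- rvar
    xc <- xm - rep(mu, each = n)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(invstd, each = n)
  ym <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d),
       rmean = rmean, rvar = rvar)
}

bn_backward <- function(g, cache, gamma) {
  d <- cache$d
  C <- d[3]
  gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)
  xhat <- cache$xhat
  n <- nrow(gm)
  ggamma <- colSums(gm * xhat)
  gbeta <- colSums(gm)
  gi <- gamma * cache$invstd
  gx <- gm * rep(gi, each = n) -
    xhat * rep(gi * ggamma / n, each = n) -
    rep(gi * gbeta / n, each = n)
  gx <- aperm(array(gx, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# 1x1 convolution; w is (Cin x Cout).
conv1x1_forward <- function(x, w, b) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  ym <- sweep(xm %*% w, 2, b, `+`)
  aperm(array(ym, c(d[1], d[2], d[4], ncol(w))), c(1, 2, 4, 3))
}

conv1x1_backward <- function(x, w, g) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = ncol(w))
  gx <- aperm(array(gm %*% t(w), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(gx = gx, gw = t(xm) %*% gm, gb = colSums(gm))
}

# Transposed convolution, kernel 2, stride 2 (learned 2x upsampling).
# w is (Cin, Cout, 4) with slice p = di + 2*dj + 1, di/dj in {0,1}.
tconv2_forward <- function(x, w, b) {
  d <- dim(x)
  h <- d[1]; ww <- d[2]; Cin <- d[3]; N <- d[4]
  Cout <- dim(w)[2]
  out <- array(0, c(2 * h, 2 * ww, Cout, N))
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = Cin)   # (h*w*N) x Cin
  for (p in 1:4) {
    di <- (p - 1) %% 2; dj <- (p - 1) %/% 2
    om <- sweep(xm %*% w[, , p, drop = TRUE], 2, b, `+`)
    out[seq(1 + di, 2 * h, 2), seq(1 + dj, 2 * ww, 2), , ] <-
      aperm(array(om, c(h, ww, N, Cout)), c(1, 2, 4, 3))
  }
  out
}

tconv2_backward <- function(x, w, g) {
  d <- dim(x)
  h <- d[1]; ww <- d[2]; Cin <- d[3]; N <- d[4]
  Cout <- dim(w)[2]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = Cin)
  gx_m <- matrix(0, nrow(xm), Cin)
  gw <- array(0, dim(w))
  gb <- numeric(Cout)
  for (p in 1:4) {
    di <- (p - 1) %% 2; dj <- (p - 1) %/% 2
    gp <- g[seq(1 + di, 2 * h, 2), seq(1 + dj, 2 * ww, 2), , , drop = FALSE]
    gm <- matrix(aperm(gp, c(1, 2, 4, 3)), ncol = Cout)
    gw[, , p] <- t(xm) %*% gm
    gb <- gb + colSums(gm)
    gx_m <- gx_m + gm %*% t(w[, , p, drop = TRUE])
  }
  gx <- aperm(array(gx_m, c(h, ww, N, Cin)), c(1, 2, 4, 3))
  list(gx = gx, gw = gw, gb = gb)
}

# Nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).
upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

upsample2_backward <- function(g) {
  d <- dim(g)
  h <- d[1] / 2; w <- d[2] / 2
  g[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    g[seq(2, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    g[seq(1, d[1], 2), seq(2, d[2], 2), , , drop = FALSE] +
    g[seq(2, d[1], 2), seq(2, d[2], 2), , , drop = FALSE]
}

# 2x2 average pooling (used to resample ground-truth fields per scale).
avgpool2 <- function(x) {
  added_n <- FALSE
  if (length(dim(x)) == 3) { x <- array(x, c(dim(x), 1)); added_n <- TRUE }
  out <- upsample2_backward(x) / 4
  if (added_n) out <- array(out, dim(out)[1:3])
  out
}

# Adam optimizer state and update.
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = state)
}
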