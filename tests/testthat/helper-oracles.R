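# Independent reference implementations used as oracles. Deliberately
# naive (per-pixel loops, closed forms); they must never share code with
# the package internals they check.

# Bilinear backward warp, scalar loop.
ref_warp <- function(img, u, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H, W)
  px <- function(i, j) {
    if (i >= 1 && i <= H && j >= 1 && j <= W) img[i, j] else fill
  }
  for (i in 1:H) for (j in 1:W) {
    r <- i + u[i, j, 1]; c <- j + u[i, j, 2]
    r0 <- floor(r); c0 <- floor(c)
    fr <- r - r0; fc <- c - c0
    out[i, j] <- (1 - fr) * (1 - fc) * px(r0, c0) +
      fr * (1 - fc) * px(r0 + 1, c0) +
      (1 - fr) * fc * px(r0, c0 + 1) +
      fr * fc * px(r0 + 1, c0 + 1)
  }
  out
}

# Per-pixel 2x2 forward-difference Jacobian determinant scan.
ref_min_jacobian <- function(u) {
  H <- dim(u)[1]; W <- dim(u)[2]
  mn <- Inf
  for (i in 1:(H - 1)) for (j in 1:(W - 1)) {
    a11 <- 1 + (u[i + 1, j, 1] - u[i, j, 1])
    a12 <- u[i, j + 1, 1] - u[i, j, 1]
    a21 <- u[i + 1, j, 2] - u[i, j, 2]
    a22 <- 1 + (u[i, j + 1, 2] - u[i, j, 2])
    mn <- min(mn, a11 * a22 - a12 * a21)
  }
  mn
}

# Exact two-sided signed-rank p by enumeration (independent of the
# package's enumeration: different loop structure and tail rule).
ref_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  vs <- apply(expand.grid(rep(list(c(0, 1)), n)), 1,
              function(s) sum(r[s == 1]))
  min(1, 2 * min(mean(vs <= v), mean(vs >= v)))
}

interior <- function(x, m) {
  d <- dim(x)
  x[(1 + m):(d[1] - m), (1 + m):(d[2] - m), , drop = FALSE]
}
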