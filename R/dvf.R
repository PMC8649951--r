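# Displacement-vector-field (DVF) algebra: random topology-preserving
# field generation, per-pixel mean removal across the 7 frames, backward
# warping, composition, and fixed-point numerical inversion.
#
# A DVF is an (H, W, 2) array of per-pixel displacements in pixels,
# channel 1 = row, channel 2 = col, backward-map convention:
# warped(x) = image(x + u(x)).

as_dvf <- function(u) {
  if (length(dim(u)) != 3 || dim(u)[3] != 2)
    t1moco_stop("t1moco_contract_error", "a DVF is an (H, W, 2) array")
  if (!all(is.finite(u)))
    t1moco_stop("t1moco_contract_error", "DVF must be finite everywhere")
  u
}

#' Bundle 7 per-frame DVFs into a set
#' @param fields Array (H, W, 2, 7) or list of 7 (H, W, 2) arrays.
#' @param mean_removed Logical; TRUE only after [remove_mean_displacement()].
#' @return Object of class `dvf_set` with `fields` (H, W, 2, 7).
#' @export
dvf_set <- function(fields, mean_removed = FALSE) {
  if (is.list(fields)) {
    if (length(fields) != 7)
      t1moco_stop("t1moco_contract_error", "a DVF set holds exactly 7 fields")
    shp <- dim(fields[[1]])
    for (f in fields)
      if (!identical(dim(as_dvf(f)), shp))
        t1moco_stop("t1moco_contract_error", "all fields must share one shape")
    arr <- array(0, c(shp, 7))
    for (k in 1:7) arr[, , , k] <- fields[[k]]
    fields <- arr
  }
  d <- dim(fields)
  if (length(d) != 4 || d[3] != 2 || d[4] != 7)
    t1moco_stop("t1moco_contract_error", "fields must be (H, W, 2, 7)")
  structure(list(fields = fields, mean_removed = isTRUE(mean_removed)),
            class = "dvf_set")
}

#' @export
print.dvf_set <- function(x, ...) {
  d <- dim(x$fields)
  cat(sprintf("DVF set: %d x %d x 2 x 7, mean_removed = %s, max |u| = %.3f px\n",
              d[1], d[2], x$mean_removed, max(abs(x$fields))))
  invisible(x)
}

# Separable Gaussian smoothing with edge renormalization (each output pixel
# averages only the in-domain part of the kernel).
gauss_smooth <- function(x, sigma) {
  k <- function(n) {
    r <- ceiling(3 * sigma)
    idx <- seq_len(n)
    m <- outer(idx, idx, function(i, j) exp(-((i - j)^2) / (2 * sigma^2)))
    m[abs(row(m) - col(m)) > r] <- 0
    m / rowSums(m)
  }
  k(nrow(x)) %*% x %*% t(k(ncol(x)))
}

#' Finite-difference Jacobian determinants of the deformation x + u(x)
#'
#' Forward differences (backward on the last row/column). A field is
#' certified topology-preserving when the minimum determinant is positive.
#'
#' @param dvf An (H, W, 2) DVF.
#' @return Matrix (H, W) of det(I + grad u).
#' @export
jacobian_determinant <- function(dvf) {
  u <- as_dvf(dvf)
  H <- dim(u)[1]; W <- dim(u)[2]
  dr <- function(m) { d <- m[c(2:H, H), ] - m[c(1:(H - 1), H - 1), ]; d }
  dc <- function(m) { d <- m[, c(2:W, W)] - m[, c(1:(W - 1), W - 1)]; d }
  u1 <- u[, , 1]; u2 <- u[, , 2]
  (1 + dr(u1)) * (1 + dc(u2)) - dc(u1) * dr(u2)
}

#' Generate a smooth random topology-preserving DVF
#'
#' Per-component white noise is smoothed with a Gaussian kernel of width
#' `smoothness_px` and rescaled so the maximum displacement magnitude is
#' `amplitude_px`. If the positive-Jacobian certificate fails, the
#' amplitude is shrunk by 0.8 up to 5 times; persistent failure is an
#' error (a folding field is never returned silently).
#'
#' @param shape Integer length-2 (H, W).
#' @param amplitude_px Maximum displacement magnitude, pixels (>= 0).
#' @param smoothness_px Gaussian smoothing width, pixels (> 0).
#' @param seed Integer seed; output is deterministic per seed.
#' @return An (H, W, 2) DVF.
#' @export
generate_random_dvf <- function(shape, amplitude_px, smoothness_px, seed = 1) {
  if (amplitude_px < 0)
    t1moco_stop("t1moco_contract_error", "amplitude_px must be >= 0")
  if (smoothness_px <= 0)
    t1moco_stop("t1moco_contract_error", "smoothness_px must be > 0")
  H <- shape[1]; W <- shape[2]
  u <- array(0, c(H, W, 2))
  if (amplitude_px == 0) return(u)
  raw <- with_seed(seed, array(rnorm(H * W * 2), c(H, W, 2)))
  for (ch in 1:2) u[, , ch] <- gauss_smooth(raw[, , ch], smoothness_px)
  mag <- sqrt(u[, , 1]^2 + u[, , 2]^2)
  mx <- max(mag)
  if (mx == 0) return(u)
  amp <- amplitude_px
  for (try in 0:5) {
    v <- u * (amp / mx)
    if (min(jacobian_determinant(v)) > 0) return(v)
    amp <- amp * 0.8
  }
  t1moco_stop("t1moco_generation_error",
              "could not generate a topology-preserving field (amplitude %.2f)",
              amplitude_px)
}

#' Remove the per-pixel mean displacement across the 7 fields
#'
#' Subtracts, at every pixel, the mean displacement over the 7 frames from
#' each field, leaving only relative displacement between frames (the
#' groupwise gauge fixing used to build training targets). Idempotent.
#'
#' @param set A [dvf_set].
#' @return A [dvf_set] with `mean_removed = TRUE`.
#' @export
remove_mean_displacement <- function(set) {
  if (!inherits(set, "dvf_set"))
    t1moco_stop("t1moco_contract_error", "expected a dvf_set")
  f <- set$fields
  m <- apply(f, c(1, 2, 3), mean)
  for (k in 1:7) f[, , , k] <- f[, , , k] - m
  dvf_set(f, mean_removed = TRUE)
}

#' Backward-warp an image by a DVF
#'
#' `warped(x) = image(x + u(x))`, bilinear interpolation; samples landing
#' outside the domain take `fill_value`. The same kernel is reused inside
#' the network's warping layers.
#'
#' @param image Matrix (H, W) or array (H, W, C).
#' @param dvf An (H, W, 2) DVF with matching spatial shape.
#' @param fill_value Constant used outside the domain.
#' @return Warped image, same shape as `image`.
#' @export
warp <- function(image, dvf, fill_value = 0) {
  u <- as_dvf(dvf)
  is_mat <- is.matrix(image)
  img <- if (is_mat) array(image, c(dim(image), 1)) else image
  if (!identical(dim(img)[1:2], dim(u)[1:2]))
    t1moco_stop("t1moco_contract_error", "image and DVF shapes disagree")
  x4 <- array(img, c(dim(img), 1))
  f4 <- array(u, c(dim(u), 1))
  out <- cpp_warp(x4, f4, fill_value)
  out <- array(out, dim(img))
  if (is_mat) out[, , 1] else out
}

#' Compose two DVFs
#'
#' Returns `c` with `c(x) = u_inner(x) + u_outer(x + u_inner(x))`, so that
#' warping by `c` equals warping by `dvf_outer` after `dvf_inner` on
#' interior pixels. The outer field is sampled bilinearly (fill 0 outside,
#' i.e. identity beyond the border).
#'
#' @param dvf_outer,dvf_inner (H, W, 2) DVFs of equal shape.
#' @return The composed (H, W, 2) DVF.
#' @export
compose <- function(dvf_outer, dvf_inner) {
  uo <- as_dvf(dvf_outer); ui <- as_dvf(dvf_inner)
  if (!identical(dim(uo), dim(ui)))
    t1moco_stop("t1moco_contract_error", "DVF shapes disagree")
  ui + warp(uo, ui, fill_value = 0)
}

#' Numerically invert a DVF by fixed-point iteration
#'
#' Iterates `v_{k+1}(x) = -u(x + v_k(x))` from `v_0 = 0` until the largest
#' update falls below `tol_px` or `max_iter` is reached, then verifies the
#' residual `compose(u, v)` on interior pixels (a margin of
#' `ceiling(max |u|) + 1` pixels) against `5 * tol_px`.
#'
#' @param dvf A topology-preserving (H, W, 2) DVF.
#' @param tol_px Convergence tolerance in pixels.
#' @param max_iter Iteration cap.
#' @return The inverse (H, W, 2) DVF.
#' @export
invert <- function(dvf, tol_px = 0.01, max_iter = 50) {
  u <- as_dvf(dvf)
  v <- array(0, dim(u))
  for (k in seq_len(max_iter)) {
    vn <- -warp(u, v, fill_value = 0)
    upd <- max(abs(vn - v))
    v <- vn
    if (upd < tol_px) break
  }
  res <- compose(u, v)
  H <- dim(u)[1]; W <- dim(u)[2]
  m <- min(ceiling(max(abs(u))) + 1, floor(min(H, W) / 4))
  interior <- res[(1 + m):(H - m), (1 + m):(W - m), , drop = FALSE]
  if (max(abs(interior)) >= 5 * tol_px)
    t1moco_stop("t1moco_inversion_error",
                "inversion residual %.4f px exceeds %.4f px",
                max(abs(interior)), 5 * tol_px)
  v
}
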