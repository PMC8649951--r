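# Synthetic short-axis cardiac phantom and its inversion-recovery-weighted
# (IRW) image stack. Stands in for restricted in-vivo training data: a
# mid-ventricular short-axis slice (blood pool inside a myocardial ring,
# body outline, a liver/stomach-like structure) with per-tissue T1/M0 and a
# magnitude inversion-recovery signal model sampled at 7 inversion times.

#' Tissue label codes used by the phantom
#'
#' Integer label codes: 0 background (air), 1 body, 2 blood pool,
#' 3 myocardium, 4 liver/stomach-like structure.
#' @return Named integer vector of label codes.
#' @export
phantom_labels <- function() {
  c(background = 0L, body = 1L, blood_pool = 2L, myocardium = 3L, liver = 4L)
}

#' Default per-tissue T1 (ms) and M0 (arbitrary units)
#'
#' Representative 1.5T-like native T1 contrast: myocardium ~950 ms, blood
#' ~1600 ms. These are configuration defaults of the simulator, not claims
#' about any acquisition. Background carries M0 = 0 (air: no signal); its T1
#' entry is a positive placeholder so every present label has T1 > 0.
#' @return List with numeric vectors `t1_ms` and `m0`, named by label code.
#' @export
default_tissue_params <- function() {
  list(
    t1_ms = c(`0` = 1, `1` = 600, `2` = 1600, `3` = 950, `4` = 800),
    m0    = c(`0` = 0, `1` = 80,  `2` = 100,  `3` = 90,  `4` = 85)
  )
}

#' Default 7-point inversion-time schedule (ms)
#'
#' A ShMOLLI-like 7-point schedule spanning ~100-4800 ms with denser early
#' sampling, covering recovery curves for T1 in roughly 200-2000 ms (at
#' most 3 samples fall before the magnitude null point, matching the
#' polarity search of the map reconstruction). The true acquisition timing
#' is heart-rate dependent and not reproduced here; the schedule is
#' configurable wherever it is consumed.
#' @return Numeric vector of 7 strictly increasing inversion times in ms.
#' @export
default_ti_schedule <- function() {
  c(100, 300, 800, 1500, 2500, 3600, 4800)
}

#' Generate a synthetic short-axis tissue label map
#'
#' Rasterizes a background/body/blood-pool/myocardium/liver geometry by
#' per-pixel distance tests: an elliptical body, a circular blood pool of
#' radius `r_inner` surrounded by a closed myocardial annulus out to
#' `r_outer`, and an elliptical liver-like structure below the heart.
#'
#' @param size Integer length-2, image size (rows, cols); at least 32x32.
#' @param centre Numeric length-2 heart centre (row, col); default image
#'   centre shifted slightly up-left, anatomy-style.
#' @param r_inner,r_outer Blood-pool and epicardial radii in pixels;
#'   `0 < r_inner < r_outer` and the outer circle must fit in the body.
#' @param jitter Amplitude (pixels) of uniform random jitter applied to the
#'   centre and radii; 0 disables randomness entirely.
#' @param tissue_params List with `t1_ms` and `m0` named by label code
#'   (see [default_tissue_params()]).
#' @param pixel_spacing Pixel spacing in mm (isotropic).
#' @param seed Integer seed; the map is deterministic given (args, seed).
#' @return A `tissue_map`: list with integer matrix `labels`, `t1_by_label`,
#'   `m0_by_label`, `pixel_spacing` and the realized `geometry`.
#' @export
make_phantom <- function(size = c(64, 64), centre = NULL,
                         r_inner = 8, r_outer = 14, jitter = 0,
                         tissue_params = default_tissue_params(),
                         pixel_spacing = 1.8, seed = 1) {
  size <- as.integer(size)
  if (length(size) != 2 || any(size < 32))
    t1moco_stop("t1moco_geometry_error", "image size must be at least 32x32")
  if (is.null(centre)) centre <- size / 2
  if (jitter > 0) {
    jit <- with_seed(derive_seed(seed, 11L), {
      list(dc = runif(2, -jitter, jitter), dr = runif(2, -jitter / 2, jitter / 2))
    })
    centre <- centre + jit$dc
    r_inner <- r_inner + jit$dr[1]
    r_outer <- r_outer + jit$dr[2]
  }
  if (!(r_inner > 0) || !(r_inner < r_outer))
    t1moco_stop("t1moco_geometry_error",
                "radii must satisfy 0 < inner (%.2f) < outer (%.2f)",
                r_inner, r_outer)
  if (centre[1] - r_outer < 1 || centre[1] + r_outer > size[1] ||
      centre[2] - r_outer < 1 || centre[2] + r_outer > size[2])
    t1moco_stop("t1moco_geometry_error",
                "outer radius %.2f does not fit inside the image", r_outer)

  H <- size[1]; W <- size[2]
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  lab <- phantom_labels()
  labels <- matrix(lab[["background"]], H, W)

  # body: ellipse filling most of the frame
  body_a <- 0.46 * H; body_b <- 0.46 * W
  body <- ((rr - H / 2) / body_a)^2 + ((cc - W / 2) / body_b)^2 <= 1
  labels[body] <- lab[["body"]]

  # liver-like structure: ellipse in the lower part of the body
  lv_c <- c(H * 0.72, W * 0.45)
  liver <- (((rr - lv_c[1]) / (0.16 * H))^2 +
            ((cc - lv_c[2]) / (0.30 * W))^2 <= 1) & body
  labels[liver] <- lab[["liver"]]

  # heart: myocardial annulus around the blood pool
  d2 <- (rr - centre[1])^2 + (cc - centre[2])^2
  labels[d2 <= r_outer^2] <- lab[["myocardium"]]
  labels[d2 <= r_inner^2] <- lab[["blood_pool"]]

  present <- sort(unique(as.vector(labels)))
  t1 <- tissue_params$t1_ms[as.character(present)]
  m0 <- tissue_params$m0[as.character(present)]
  if (anyNA(t1) || anyNA(m0) || any(t1 <= 0) || any(m0 < 0))
    t1moco_stop("t1moco_data_error",
                "every present label needs T1 > 0 and M0 >= 0")

  structure(list(labels = labels,
                 t1_by_label = tissue_params$t1_ms,
                 m0_by_label = tissue_params$m0,
                 pixel_spacing = pixel_spacing,
                 geometry = list(centre = centre, r_inner = r_inner,
                                 r_outer = r_outer)),
            class = "tissue_map")
}

#' Per-pixel ground-truth T1 and M0 images for a tissue map
#' @param tissue_map A `tissue_map`.
#' @return List with matrices `t1_ms` and `m0`.
#' @export
tissue_truth <- function(tissue_map) {
  key <- as.character(tissue_map$labels)
  H <- nrow(tissue_map$labels); W <- ncol(tissue_map$labels)
  list(t1_ms = matrix(tissue_map$t1_by_label[key], H, W),
       m0 = matrix(tissue_map$m0_by_label[key], H, W))
}

#' Magnitude inversion-recovery signal
#'
#' The three-parameter magnitude model `|A - B exp(-TI/T1*)|`. The
#' simulator uses A = M0, B = 2 M0 (perfect inversion), for which the
#' apparent T1* equals the true T1 under the Look-Locker correction
#' T1 = T1* (B/A - 1).
#'
#' @param ti Inversion time(s), ms.
#' @param a,b,t1_star Model parameters (ms for `t1_star`).
#' @return Signal magnitude(s), same shape as `ti`.
#' @export
ir_signal <- function(ti, a, b, t1_star) {
  abs(a - b * exp(-ti / t1_star))
}

#' Simulate the 7 inversion-recovery-weighted images of a tissue map
#'
#' Evaluates the magnitude inversion-recovery model per pixel at each of
#' the 7 inversion times; optional noise is zero-mean Gaussian applied to
#' the magnitude followed by taking the absolute value (a cheap Rician
#' surrogate that preserves non-negativity).
#'
#' @param tissue_map A `tissue_map`.
#' @param tis 7 inversion times in ms, all positive.
#' @param noise_sigma Noise standard deviation in M0 units; 0 = noiseless.
#' @param seed Integer seed for the noise stream.
#' @return An [irw_stack] whose `meta` carries the ground-truth T1/M0
#'   images, the label map and the seed.
#' @export
simulate_irw <- function(tissue_map, tis = default_ti_schedule(),
                         noise_sigma = 0, seed = 1) {
  if (length(tis) != 7)
    t1moco_stop("t1moco_contract_error",
                "exactly 7 inversion times required, got %d", length(tis))
  if (any(tis <= 0)) t1moco_stop("t1moco_contract_error", "all TIs must be > 0")
  if (noise_sigma < 0) t1moco_stop("t1moco_contract_error", "noise_sigma >= 0")
  tis <- sort(tis)
  truth <- tissue_truth(tissue_map)
  H <- nrow(tissue_map$labels); W <- ncol(tissue_map$labels)
  images <- array(0, c(H, W, 7))
  for (k in 1:7)
    images[, , k] <- ir_signal(tis[k], truth$m0, 2 * truth$m0, truth$t1_ms)
  if (noise_sigma > 0) {
    noise <- with_seed(derive_seed(seed, 23L),
                       array(rnorm(length(images), 0, noise_sigma), dim(images)))
    images <- abs(images + noise)
  }
  irw_stack(images, tis, pixel_spacing = tissue_map$pixel_spacing,
            meta = list(source = "phantom", seed = seed,
                        noise_sigma = noise_sigma,
                        t1_true = truth$t1_ms, m0_true = truth$m0,
                        labels = tissue_map$labels))
}

#' Construct and validate an IRW image stack
#'
#' The registration input/output unit: exactly 7 co-located 2-D magnitude
#' images with their inversion times.
#'
#' @param images Array (H, W, 7) of finite, non-negative intensities.
#' @param tis 7 inversion times (ms); stored sorted ascending, frames
#'   reordered along with them.
#' @param pixel_spacing Pixel spacing in mm.
#' @param meta Free-form provenance list.
#' @return Object of class `irw_stack`.
#' @export
irw_stack <- function(images, tis, pixel_spacing = 1.8, meta = list()) {
  if (length(dim(images)) != 3 || dim(images)[3] != 7)
    t1moco_stop("t1moco_contract_error",
                "an IRW stack has exactly 7 frames, got %s",
                paste(dim(images), collapse = "x"))
  if (length(tis) != 7)
    t1moco_stop("t1moco_contract_error", "7 inversion times required")
  if (!all(is.finite(images)) || any(images < 0))
    t1moco_stop("t1moco_contract_error",
                "intensities must be finite and non-negative (magnitude data)")
  ord <- order(tis)
  tis <- tis[ord]
  if (any(diff(tis) <= 0))
    t1moco_stop("t1moco_contract_error", "TIs must be strictly increasing")
  images <- images[, , ord, drop = FALSE]
  structure(list(images = images, tis = as.numeric(tis),
                 pixel_spacing = pixel_spacing, meta = meta),
            class = "irw_stack")
}

#' @export
print.irw_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("IRW stack: %d x %d, 7 frames, TI %s ms, spacing %.2f mm\n",
              d[1], d[2], paste(round(x$tis), collapse = "/"),
              x$pixel_spacing))
  invisible(x)
}

#' @export
print.tissue_map <- function(x, ...) {
  cat(sprintf("tissue map: %d x %d, labels {%s}\n",
              nrow(x$labels), ncol(x$labels),
              paste(sort(unique(as.vector(x$labels))), collapse = ",")))
  invisible(x)
}
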