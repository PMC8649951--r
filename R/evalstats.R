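# Evaluation statistics: inverse-variance pooling of observer scores and
# its standard error, duplicate-based intra-observer SD, paired Wilcoxon
# signed-rank comparison, and DVF-recovery (endpoint error) metrics for
# synthetic ground truth.

#' Inverse-variance weighted observer score and its standard error
#'
#' Pools per-case scores from several observers with weights
#' `W_i = 1 / sigma_i^2` (sigma_i = each observer's intra-observer SD,
#' estimated from duplicated cases): `Xbar = sum(W_i X_i) / sum(W_i)` per
#' case, and the panel-level expected standard error of the weighted
#' average `SE = (sum W_i)^(-1/2)`. With equal sigmas this reduces to the
#' plain mean and `SE = sigma / sqrt(n)`.
#'
#' @param scores_per_observer Matrix (cases x observers) or numeric vector
#'   (one case) of scores on the 0-100 scale.
#' @param sigmas Per-observer intra-observer SDs, all > 0.
#' @return List with `xbar` (per-case pooled scores), `se` (single value),
#'   `weights`.
#' @export
pooled_score <- function(scores_per_observer, sigmas) {
  if (is.vector(scores_per_observer))
    scores_per_observer <- matrix(scores_per_observer, nrow = 1)
  nobs <- ncol(scores_per_observer)
  if (nobs < 2)
    t1moco_stop("t1moco_contract_error", "need >= 2 observers")
  if (length(sigmas) != nobs)
    t1moco_stop("t1moco_contract_error", "one sigma per observer required")
  if (any(sigmas <= 0))
    t1moco_stop("t1moco_contract_error", "all sigmas must be > 0")
  w <- 1 / sigmas^2
  xbar <- as.vector(scores_per_observer %*% w) / sum(w)
  list(xbar = xbar, se = sum(w)^(-1 / 2), weights = w)
}

#' Intra-observer SD from duplicated scorings
#'
#' Within-subject SD from paired duplicates:
#' `sigma = sqrt( sum(d_j^2) / (2 m) )` over the m pairs' differences d_j.
#'
#' @param first_scores,repeat_scores Paired numeric vectors of equal
#'   length, at least 2.
#' @return The estimated sigma (0 flags perfect repeatability; a zero
#'   sigma cannot feed [pooled_score()]).
#' @export
intra_observer_sd <- function(first_scores, repeat_scores) {
  if (length(first_scores) != length(repeat_scores))
    t1moco_stop("t1moco_contract_error", "paired vectors must match in length")
  if (length(first_scores) < 2)
    t1moco_stop("t1moco_contract_error", "need >= 2 duplicate pairs")
  d <- first_scores - repeat_scores
  sqrt(sum(d^2) / (2 * length(d)))
}

# Exact two-sided signed-rank p-value by enumeration of all sign
# assignments of the (possibly tied, average-ranked) absolute differences.
wilcoxon_exact_p <- function(ranks, v_obs) {
  n <- length(ranks)
  stats_all <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    stats_all[m + 1] <- sum(ranks[bitwAnd(bitwShiftR(m, 0:(n - 1)), 1L) == 1L])
  }
  mu <- sum(ranks) / 2
  # two-sided: double the smaller tail (symmetric null), capped at 1
  p_low <- mean(stats_all <= v_obs)
  p_high <- mean(stats_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. Zero differences are
#' dropped; ties take average ranks. For `n <= exact_limit` the p-value is
#' exact by enumeration of all sign assignments (handles ties exactly);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param before,after Equal-length paired numeric vectors; at least 5
#'   non-zero differences required.
#' @param exact_limit Largest n for exact enumeration (default 14).
#' @return List with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n` (pairs used), `method`, `test_performed`. When every difference
#'   is zero, `test_performed` is FALSE and no p-value is produced.
#' @export
paired_wilcoxon <- function(before, after, exact_limit = 14) {
  if (length(before) != length(after))
    t1moco_stop("t1moco_contract_error", "paired vectors must match in length")
  d <- after - before
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                method = "none", test_performed = FALSE))
  n <- length(d)
  if (n < 5)
    t1moco_stop("t1moco_contract_error",
                "need >= 5 non-zero differences, got %d", n)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- wilcoxon_exact_p(r, v)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n = n, method = method,
       test_performed = TRUE)
}

#' Endpoint-error metrics between predicted and ground-truth DVF sets
#'
#' Endpoint error (EPE) is the Euclidean norm of the per-pixel, per-frame
#' difference between predicted and true displacement vectors; the
#' synthetic-data surrogate for human motion scores.
#'
#' @param pred_set,gt_set [dvf_set]s of matching shape.
#' @param mask Optional non-empty logical matrix; metrics are computed
#'   over mask pixels only (default: everywhere).
#' @return List with `mean_epe_px`, `max_epe_px`, `frame_epe` (length-7
#'   per-frame means).
#' @export
dvf_recovery_metrics <- function(pred_set, gt_set, mask = NULL) {
  p <- pred_set$fields; g <- gt_set$fields
  if (!identical(dim(p), dim(g)))
    t1moco_stop("t1moco_contract_error", "DVF set shapes disagree")
  H <- dim(p)[1]; W <- dim(p)[2]
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  if (!identical(dim(mask), c(H, W)))
    t1moco_stop("t1moco_contract_error", "mask shape must match the fields")
  if (!any(mask))
    t1moco_stop("t1moco_contract_error", "mask is empty")
  epe <- sqrt((p[, , 1, ] - g[, , 1, ])^2 + (p[, , 2, ] - g[, , 2, ])^2)
  frame_epe <- vapply(1:7, function(k) mean(epe[, , k][mask]), 1)
  list(mean_epe_px = mean(frame_epe), max_epe_px = max(apply(epe, 3, function(m) max(m[mask]))),
       frame_epe = frame_epe)
}
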