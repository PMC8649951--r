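---
title: "Groupwise motion correction for cardiac T1 mapping: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Groupwise motion correction for cardiac T1 mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1moco)
```

## The problem

ShMOLLI-style myocardial T1 mapping acquires seven inversion-recovery-weighted
(IRW) magnitude images at increasing inversion times TI within one breath-hold
and fits, pixel by pixel, an exponential recovery curve. Respiratory motion
misaligns the seven frames, so a pixel's seven samples no longer come from one
tissue; the fitted T1 is biased and the per-pixel coefficient of explained
variance (the R² map) develops dark bands that radiologists use to flag
unusable maps.

`t1moco` treats the correction as *groupwise inverse-deformation estimation*:
given the seven frames, predict for each frame the displacement vector field
(DVF) that undoes its motion, warp the frames by their fields, and only then
reconstruct the T1 and R² maps. No frame is designated as the reference; the
gauge is fixed by training targets whose per-pixel mean displacement across
the seven frames is zero.

## Signal model and map reconstruction

The simulator and the fitting share the three-parameter magnitude model

$$ S(TI) = | A - B \exp(-TI / T_1^*) |, \qquad
   T_1 = T_1^*\left(\tfrac{B}{A} - 1\right), $$

with $A = M_0$, $B = 2 M_0$ in the simulator (perfect inversion, so
$T_1 = T_1^*$). The apparent $T_1^*$ is searched in $[50, 5000]$ ms. For a
fixed $T_1^*$ the model is linear in $(A, B)$, so the per-pixel fit is a
one-dimensional search: a 64-point log-spaced grid followed by three shrinking
local grids, solved in closed form at each grid point, vectorized over all
pixels. Magnitude data hide the sign of the pre-null samples, so polarity
splits $k \in \{0, 1, 2, 3\}$ (sign-flip the $k$ earliest-TI samples) are all
fitted and the candidate with the highest R² wins, where
$R^2 = 1 - SS_{res}/SS_{tot}$ about the mean of the polarity-restored samples
(the conventional definition; the original reconstruction library's exact
definition is not published). R² may be negative for terrible fits and is
reported as-is. Constant signal vectors are flagged `degenerate`; candidates
with non-positive $A$ or $T_1$ are rejected and, if none survives, the pixel
is flagged `failed` — never silently zero-filled.

The default 7-point TI schedule (100, 300, 800, 1500, 2500, 3600, 4800 ms)
spans the recovery of T1s in roughly 200–2000 ms with at most three samples
before the magnitude null point for the default tissue T1s, matching the
4-way polarity search. Real ShMOLLI timing is heart-rate dependent and is
*not* reproduced; the schedule is a configurable stand-in.

## The phantom: what it emulates, what it does not

`make_phantom()` rasterizes a short-axis slice: an elliptical body, a
circular blood pool (default T1 1600 ms) inside a closed myocardial annulus
(950 ms), and a liver-like structure (800 ms); background has $M_0 = 0$.
These T1/M0 values are 1.5T-like configuration defaults, not claims. Optional
noise is $|S + \mathcal{N}(0, \sigma)|$ — a cheap Rician surrogate that
preserves non-negativity without simulating complex data. Geometry jitter
(centre and radii) provides anatomical variability across training stacks.

Deliberately absent: cardiac contraction, through-plane motion (not
correctable by 2-D registration), partial-Fourier/k-space artefacts,
off-resonance and fat effects. A green end-to-end test therefore establishes
that the pipeline corrects smooth in-plane deformations of piecewise-constant
anatomy at the stated noise level — not that it corrects clinical data.

## DVF algebra

Displacements are stored in pixels, `(row, col)` order, backward-map
convention — `warped(x) = image(x + u(x))` — with bilinear interpolation and
constant fill outside the domain; one convention everywhere. Random fields
are Gaussian-smoothed white noise (width `smoothness_px`, default 12 px)
rescaled to a maximum magnitude `amplitude_px`; a field is accepted only if
its finite-difference Jacobian `det(I + ∇u)` is positive everywhere, with up
to five ×0.8 amplitude shrinks before a generation error — a folding field is
never returned. Inversion is the fixed-point iteration
$v_{k+1}(x) = -u(x + v_k(x))$, verified post hoc through the composition
residual on interior pixels. Ground-truth inverses for training are produced
by this inversion, not by negation, which is wrong for non-rigid fields.

Amplitude (3 px) and smoothness (12 px) defaults were chosen once to mimic
breath-hold-failure-scale drift at the phantom's 1.8 mm pixel spacing; they
are not taken from published deformation statistics.

## Network

The registration network is a U-Net-like encoder–decoder over the 7-frame
stack with warping layers at each of 4 scales:

* **Encoder** — Siamese: each frame passes through the same
  3×3 conv → batch-norm → leaky-ReLU (×2) → 2×2 max-pool stack, frames folded
  into the batch dimension. Skip features therefore stay frame-grouped, which
  resolves an ambiguity in the published figure: each frame's feature block
  is warped by *that frame's* current DVF estimate.
* **Decoder** — coarse-to-fine. At the coarsest scale a zero-initialized 1×1
  head emits the first DVF estimate (so the untrained network is exactly an
  identity corrector). At each finer scale the decoder consumes the
  transposed-conv-upsampled features, the upsampled DVF (values doubled, so
  fields stay in units of their own grid), and the warped skip features, and
  adds a residual correction from another zero-initialized head.
* **Loss** — mean over scales of the MSE between each scale's prediction and
  the ground truth resampled to that scale (2×2 average pooling per halving,
  displacements divided by 2). Resampling ground truth rather than upsampling
  predictions keeps the per-scale MSEs comparable.

One deliberate asymmetry: the backward pass does not differentiate through
the warping layer with respect to its *flow* argument. The flow also enters
the decoder as explicit channels and receives direct supervision at its own
scale, so the gradient path exists; detaching the sampling positions removes
the one non-smooth term and is standard practice in coarse-to-fine flow
estimation. The gradient test in the suite verifies all remaining gradients
against finite differences to ~1e-8 relative error under a constant flow.

Batch-norm statistics are frozen at inference; there is no dropout.

## Training

Training is self-supervised: seven random fields are drawn per motion-free
stack, their per-pixel mean is removed (only relative motion is observable),
the frames are warped, and the network is trained to predict the mean-removed
frame-wise inverses. Published regime where stated: Adam at 0.001, mini-batch
4, 10 % validation split, early stopping after 50 epochs without improvement,
zero-padding to a common size, pooled-quantile intensity normalization. Items
the publication leaves open were fixed as: reduce-on-plateau scheduler
(factor 0.5, patience 10, floor 1e-5); "no improvement" means no decrease of
at least 1e-6; quantile bounds (0.01, 0.99) applied to all 7 frames pooled —
per-frame normalization would destroy the inversion-recovery intensity
ordering that carries the signal. Per-pair deformation amplitudes are drawn
uniformly from (0, `amplitude_px`] so nearly-aligned stacks stay inside the
training distribution and the trained model behaves as a near-no-op on clean
data. Deformations are resampled fresh every epoch by default; the
`fixed_pairs` mode generates them once and caches them, which the desk-scale
test runs use to stay inside their CPU budget.

The full-scale regime (384×384, ~1,500 stacks, patience 50, ~48 h on a GPU)
is configurable but out of scope here; the test suite trains a reduced model
(64×64, ~200 stacks, base width 8, learning rate 0.002, bounded epochs) in a
few minutes on one CPU. The higher desk learning rate compensates for the
~30× fewer optimizer steps; 0.001 remains the `train_config()` default.

## Evaluation statistics

Human motion scores are replaced on synthetic data by the endpoint error
(EPE) against the known fields, plus an automated R² severity proxy: the
fraction of myocardial pixels with R² below a threshold (default 0.95). With
noiseless synthetic stacks the proxy is degenerate (R² ≈ 1 even under
motion); evaluation therefore uses a realistic noise level (σ = 2 % of blood
M0), where motion produces genuine dark-band fractions that correction must
reduce.

The observer model: per-observer intra-observer SDs σᵢ from duplicated
scorings, `σ = sqrt(Σd²/2m)`; weights `Wᵢ = 1/σᵢ²`; pooled per-case score
`X̄ = ΣWᵢXᵢ/ΣWᵢ`; panel standard error `SE = (ΣWᵢ)^(-1/2)`. The published SE
formula is typographically ambiguous; this reading reproduces the published
value from the published SDs to within their printed rounding. With the
published SDs:

```{r}
pooled_score(c(50, 50, 50), sigmas = c(10.6, 17.3, 21.9))$se
```

Paired comparisons use a two-sided Wilcoxon signed-rank test — exact by
enumeration of sign assignments up to n = 14 (ties handled exactly via
average ranks), normal approximation with tie and continuity corrections
beyond.

## Numerical details worth knowing

* All arithmetic is double precision; convolutions run through im2col + BLAS
  in C++, everything else in R. Results are deterministic for a fixed seed on
  a fixed BLAS.
* `pad_to_size()` centres with ties broken toward bottom/right and records
  offsets, so crop-back is exact.
* `invert()` declares failure (with the residual) instead of returning a
  non-convergent field; `generate_random_dvf()` does the same for folding
  fields.
* Quantile normalization of a constant image returns all zeros (degenerate
  range rule).
* Bilinear interpolation is exact for affine images and integer shifts; on
  images with step edges any warp/unwarp round trip errs by O(step) at edge
  crossings. Oracles that assert interpolation-level tolerances therefore use
  band-limited imagery; phantom round trips are gated on mean error.

## Known limitations

* 2-D, single-slice, 7-frame only; no diffeomorphic parameterization.
* The phantom's homogeneous tissue interiors make interior displacement
  observable only through the smoothness of the field family, and its sharp
  edges are harsher on interpolation than real MR texture.
* Training at desk scale stops far from convergence; the end-to-end test
  establishes direction and magnitude of improvement, not the published
  effect size, whose inputs (UK Biobank scans, human observers) are
  access-restricted.
* DICOM and NIfTI I/O are not included: no reader exists in the target R
  environment, and the fixture container plus a plain-text frame-directory
  format cover every documented workflow here.
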