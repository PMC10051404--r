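---
title: "Coarse-to-fine segmentation with uncertainty-guided patch refinement: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(patchrefine)
```

This vignette is the package's own account of the method it implements:
the model, its assumptions, the parameters that matter, the numerical
choices made where the design was genuinely open, what the synthetic
fixtures do and do not establish, and known limitations. It states no
empirical result that the test suite does not itself compute.

## 1. The procedure

Binary semantic segmentation assigns each pixel a foreground probability.
The cost of a fully convolutional forward pass scales with input area —
counted as multiply-accumulates (MACs), doubling each image side quadruples
it — yet most pixels in typical biomedical or street-scene imagery are easy
background. The two-stage procedure exploits this:

1. **Coarse pass** — Model 1 (`f¹`) processes the image downscaled by the
   grid factor; its probability map is upscaled back to full resolution
   (both directions bilinear).
2. **Scoring** — the image is partitioned by a `rows × cols` grid of
   contiguous, non-overlapping patches (0-based `(i, j)` indices, half-open
   rectangles, row-major: a convention this package fixes globally).
   Each patch is scored by the *mean per-pixel uncertainty* of its crop of
   the upscaled coarse map.
3. **Refinement** — patches whose score reaches the selection threshold are
   re-segmented at full resolution by Model 2 (`f²`), and their crops
   *replace* (not blend into) the coarse probabilities. The assignment
   semantics of the write-back are replacement; everything outside refined
   patches is bit-exactly the coarse map, which the tests assert.

For a square grid of `P` patches on a square image, one patch and the
downscaled image have the same shape, so both models share one input size
and one per-pass cost. Inference cost is `(1 + #refined)` passes instead of
the `P` passes of patch-everything processing, or one pass at `P×` the
area.

### Assumptions

- **Uncertainty locates difficulty.** The procedure helps only where the
  coarse model's uncertainty concentrates in the regions it actually gets
  wrong. The synthetic validation hook (section 5) tests exactly this
  premise.
- **Difficulty is spatially clustered** at roughly patch granularity. With
  difficulty spread uniformly, every patch scores alike and selection
  degenerates to all-or-nothing.
- **Binary task.** Multi-class segmentation would need a different
  uncertainty (e.g. full categorical entropy) and head; it is out of scope.

## 2. Uncertainty variants

Two per-pixel uncertainties are implemented:

- `full_entropy` (default): `H(p) = −p log₂ p − (1−p) log₂ (1−p)`,
  symmetric, maximal (1) at `p = 0.5`.
- `paper`: the one-sided surprisal `u(p) = −p log₂ p`, which peaks at
  `p = 1/e ≈ 0.368` with maximum `log₂(e)/e ≈ 0.531` and rates a confident
  *background* pixel (`p → 0`) mildly uncertain while a confident
  foreground pixel (`p → 1`) is certain.

The one-sided form appears in the literature this package follows, but it
contradicts the usual gloss that uncertainty should be largest for
probabilities near 0.5, and its bound of ≈0.531 makes high nominal
thresholds (e.g. 0.75) unreachable on a raw scale. Full binary entropy has
neither defect, so it is the default; the one-sided form is preserved as an
explicit variant for comparability.

**Threshold normalization.** Selection thresholds are interpreted on a
`[0, 1]` scale after dividing scores by the active variant's maximum
(`u_max`). This makes the endpoints exact under either variant — threshold
1 selects only saturated patches (in practice: nothing), threshold 0
selects everything — and keeps threshold sweeps comparable across variants.
Whether raw or normalized scores were thresholded in the original
experiments is not determinable from the source; normalization is this
package's choice, applied consistently. The comparison is `≥`.

Two further conventions, chosen for reproducibility where the source is
silent: weighted sampling with an all-zero score vector falls back to
uniform (avoiding 0/0), and arg-max sampling breaks ties by the smallest
row-major index.

## 3. Grids, interpolation, geometry

`make_grid(h, w, P)` must tile the image exactly. Among factorizations
`rows × cols = P` with `rows | h` and `cols | w`, it picks the one whose
patch aspect ratio is closest (in log-ratio distance) to the image's, so
square counts on square images give the expected `√P × √P` lattice. The
tie between transposed factorizations (e.g. 8×16 vs 16×8 for 128 patches
on a square image) resolves toward more grid rows. Non-square grids break
the shared-input-shape property; the pipeline still runs but warns.

Bilinear resizing uses the pixel-area ("align-corners-false") mapping
`src = (dst + 0.5)·scale − 0.5`, implemented separably as interpolation
matrices `Y = R_r X R_cᵀ`. Every row of an interpolation matrix sums to 1,
so constants — and hence the `[0, 1]` range of probability maps — are
preserved exactly, and the transpose gives the exact gradient for
backpropagation. Masks are resized by nearest neighbour so label sets stay
closed. Crops are copies, never views: Stage-2 refinement can never alias
Stage-1 buffers.

Context fusion crops the sub-region of Stage 1's low-resolution penultimate
activation spatially corresponding to the patch, using proportional
coordinates with floor rounding over half-open intervals, then bilinearly
resizes it to Stage 2's penultimate shape for elementwise addition. The
Stage-1 activation is computed once per image during the coarse pass, never
per patch — recomputing it per patch would defeat the efficiency goal.

## 4. Models, training, accounting

Because no deep-learning runtime is available in the target R stack, the
models run on a small computational-graph engine in plain R: im2col
convolutions executed as BLAS matrix products, manual reverse-mode
differentiation (verified against central finite differences in the test
suite at tolerance 1e-5), and Adam. The engine is slow by GPU standards but
exact, dependency-free, and fast enough for desk scale.

- **`tiny`** (default everywhere in tests): a 4,881-parameter
  encoder–decoder (3×3 convs, one stride-2 stage, bilinear upsample back to
  input size, 1×1 prediction head). The *penultimate layer* — the site of
  context fusion — is defined as the input to that final 1×1 convolution.
- **`fcn`, `deeplabv3`, `unet`, `segnet`**: ResNet-50-encoder reference
  designs. They satisfy the forward contract (checked at small inputs) and
  exact analytic parameter/MAC accounting; training them in this engine is
  unsupported (pool/concat layers are forward-only) and would be
  impractical anyway. Their BatchNorm layers are affine-only (`γ, β`, no
  batch statistics): parameter counts are unaffected, and these backbones
  exist for accounting and contract checks, not for producing calibrated
  predictions. FCN and DeepLab-v3 include the conventional auxiliary head
  on the stride-16 stage, which is what brings their totals to the
  reference magnitudes (35.3 M / 42.0 M); the encoder alone counts
  23,508,032 ≈ 23.5 M parameters, which the acceptance suite asserts
  exactly.
- **MAC convention**: `k²·c_in·c_out·h_out·w_out` per convolution
  (dilation-independent), `in·out` per dense layer; normalization, pooling,
  resizing and activations excluded. Under this convention fully
  convolutional costs scale with area, which the acceptance suite checks as
  the quadrupling law within [3.8, 4.2] over three doublings.

**Training recipe.** Focal loss
`−α_t (1−p_t)^γ log p_t` with `γ = 2` (the canonical focusing value; the
source names the loss without hyperparameters) and `α = 1` (no class
weighting is mentioned anywhere, so none is applied; both configurable).
Probabilities are clamped to `[1e-7, 1−1e-7]` so exact 0/1 stay finite;
`γ = 0, α = 1` provably reduces to mean binary cross-entropy, which the
tests assert against an independent implementation. Optimizer: Adam,
default `β₁ = 0.9, β₂ = 0.999, ε = 1e-8`, learning rate `1e-4`, 20
epochs. Augmentation: horizontal flip (p = 0.5), brightness and contrast
jitter with factors drawn uniformly from `[0.9, 1.1]` ("by 0.1" is read as
a multiplicative amplitude), and a ≤10% translation realized as
upscale-then-crop, geometric transforms applied identically to image and
mask, photometric only to the image.

Stage 1 is trained to completion and *frozen*; Stage 2 is then trained with
exactly one patch per image per epoch, sampled by the configured strategy
from scores recomputed on the augmented image each epoch (the only
self-consistent choice, since augmentation changes the image the frozen
Stage 1 sees). End-to-end joint training is explicitly out of scope.
Fine-tuning (`init_stage2_from_stage1`) is a deep copy — mutating Stage 2
can never touch Stage 1, and the tests hash-compare Stage-1 weights before
and after Stage-2 training.

**Desk-scale training parameters.** The reference recipe (`lr = 1e-4`,
batch ≥ 4) targets ImageNet-pretrained ResNet-50 backbones on
thousand-image datasets. The desk-scale world used throughout the tests —
`tiny` models trained from scratch on 20 images of 96×96 — needs a larger
step (`1e-3`) and per-image updates (`batch_size = 1`): with batch 4 a
20-image epoch yields only 5 optimizer steps and the coarse model is still
far from converged after 20 epochs, leaving probabilities so uniformly
mid-range that patch scores cannot separate hard from easy regions. These
two values were fixed once on that reasoning and are used by every
desk-scale test; the package defaults remain the reference values.

## 5. The synthetic world

`generate_pair()` renders cell-like blobs — radially perturbed rotated
ellipses (four random sinusoidal harmonics) — on a grey background, with
the binary mask being the *exact* rasterized blob union. Difficulty is
injected at the granularity of a reference 4×4 patch grid: a fixed fraction
(default 1/4) of cells is "hard", and there blobs get rough boundaries
(perturbation amplitude 0.45 vs 0.08), pixels get low foreground contrast
(0.12 vs 0.35) and 3× texture noise (σ 0.12 vs 0.04). Defaults: 96×96
images, radii 7–13 px, foreground target 18% — inside the 6.6–31.8%
foreground range of typical binary benchmarks; blobs are added until the
target is crossed, so the realized fraction tracks it to within a few
percent, which a Monte-Carlo test checks over 200 images. Everything is a
pure function of `(seed, index)`, asserted bit-exactly.

The low-contrast choice for hard cells is deliberate: independent pixel
noise averages away under the coarse pass's 4× downscale, but contrast does
not, so contrast is what makes a cell *stay* hard for Stage 1 — the
property the whole method rests on. The validation hook trains a Stage-1
model and checks (Mann–Whitney, one-sided, α = 0.05, 55 fresh images) that
hard cells score higher patch uncertainty than easy cells.

What a green synthetic suite does **not** establish: real data has no
grid-aligned difficulty (the alignment concentrates refinement benefit into
selectable patches by construction), no covariate shift between train and
test, single-channel intensity rather than RGB texture, and desk-scale
models/datasets orders of magnitude smaller than production ones. Green
tests validate the *mechanics and the qualitative orderings* (refining all
patches beats refining none; disabling fine-tuning or context does not
help), not any real-world Dice level.

## 6. Numerical and degenerate-input choices

- Masks are binarized from probabilities at 0.5; Dice of two empty masks is
  defined as 1; per-dataset Dice is the unweighted mean of per-image Dice
  (macro pooling).
- Evaluation cost is reported analytically (Stage-1 MACs + #refined ×
  Stage-2 MACs, affine in the number of refined patches and asserted as
  such); wall-clock is hardware-dependent and never used in tests.
- A 1×1 grid with threshold 0 and shared weights reduces the pipeline to a
  single-model prediction, asserted to 1e-12 — the degenerate anchor that
  ties the two-stage path to the plain path.
- Images/masks/probability maps are stored as netpbm PNM (8-bit, plus
  16-bit big-endian PGM for probabilities, `value = round(p·65535)`): the
  target R stack guarantees no PNG codec, and PNM preserves the same
  quantization semantics in a format every imaging toolchain reads.
- Checkpoints are JSON with full-precision weights plus architecture,
  input size and seed — text-only and bit-exact on reload.

## 7. Known limitations

- Patches are uniformly distributed and contiguous; objects cut by patch
  borders are refined piecewise with no overlap blending (flexible
  patching is explicitly future work).
- The engine is single-threaded R: heavy backbones are accounted and
  contract-checked, not trained.
- Per-epoch scores for Stage-2 sampling require one coarse pass per image
  per epoch; for frozen Stage 1 *without* augmentation these could be
  cached, an optimization not taken for the sake of one code path.
- The `paper` uncertainty variant and the normalized-threshold convention
  interact: raw-scale thresholds above ≈0.531 are unreachable under that
  variant, which is precisely why normalization is applied.
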