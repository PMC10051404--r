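# patchrefine

Two-stage coarse-to-fine binary semantic segmentation with
uncertainty-guided patch refinement, for people who need segmentation under
a compute budget: microscopy and biomedical imaging pipelines, embedded
deployments, or any setting where most of an image is easy and spending the
same effort on every pixel is wasteful.

## The method

A conventional fully convolutional segmenter spends identical arithmetic on
every pixel, although the cost of a forward pass grows with input area
(doubling each side quadruples the multiply-accumulates). `patchrefine`
instead runs two models:

1. **Coarse pass.** Model 1 segments a downscaled copy of the image,
   `p̂ = s↑(f¹(s↓(x)))`, where `s↓`/`s↑` are bilinear interpolations.
2. **Patch scoring.** The image is partitioned into a grid of contiguous
   patches. Each patch `(i, j)` receives the mean per-pixel prediction
   uncertainty of its crop of `p̂`. The default uncertainty is binary
   Shannon entropy `H(p) = −p log₂ p − (1−p) log₂ (1−p)` (maximal at
   `p = 0.5`); the one-sided surprisal `u(p) = −p log₂ p` is available as a
   variant.
3. **Refinement.** Patches scoring at least `τ · u_max` (a threshold on a
   [0, 1]-normalized scale, so `τ = 0` refines everything and `τ = 1`
   nothing) are re-segmented at full resolution by Model 2, and their crops
   replace the coarse probabilities: `c_{i,j}(p̂) ← f²(c_{i,j}(x))`.

For a square grid of `P` patches on a square image the two models share one
input shape (the image downscaled by `√P` equals one patch), so Stage-1 and
Stage-2 forward passes cost the same; total inference cost is
`(1 + #refined) ×` that cost instead of `P ×`.

Training (Adam `1e-4`, 20 epochs, focal loss
`−α_t (1−p_t)^γ log p_t` with `γ = 2`, horizontal flips, ±0.1
brightness/contrast jitter, 10% translation via upscale-then-crop) adds
three couplings between the stages:

- **Fine-tuning:** Model 2 is initialized from trained Model 1's weights.
- **Context fusion:** the patch-aligned crop of Model 1's penultimate
  activation is resized and added elementwise to Model 2's penultimate
  layer.
- **Uncertainty-driven sampling:** each epoch, one patch per image is
  sampled for Model 2 — uniformly (`random`), proportionally to patch
  uncertainty (`weighted`), or the arg-max patch (`highest`).

Evaluation is the Dice coefficient `2|A∩B| / (|A|+|B|)`; cost is reported
as analytic multiply-accumulate counts, never wall clock.

## Worked example

Desk-scale end-to-end run on generated cell-like images whose difficulty is
spatially heterogeneous (a quarter of the grid cells get low-contrast,
noisy, rough-boundary blobs):

```r
library(patchrefine)

cfg   <- synthetic_config(seed = 1)
train <- lapply(generate_dataset(cfg, 20), function(p) p[c("image", "mask")])
test  <- lapply(generate_dataset(cfg, 8, first_index = 21),
                function(p) p[c("image", "mask")])

grid <- make_grid(96, 96, 16)
#> patch_grid: 4 x 4 patches of 24 x 24 px over a 96 x 96 image

tc <- train_config(learning_rate = 1e-3, epochs = 20, batch_size = 1,
                   image_size = c(96, 96), seed = 1)
m1 <- build_model("tiny", c(grid$patch_h, grid$patch_w), in_channels = 1, seed = 1)
m1 <- train_stage1(m1, train, grid, tc)

sel <- selection_config("weighted", threshold = 0.25, seed = 1)
m2  <- train_stage2(m1, init_stage2_from_stage1(m1), train, grid, sel, tc,
                    context = TRUE)

evaluate_pipeline(m1, m2, test, grid, sel, context = TRUE)
#> eval_report (two_stage): 8 images, mean Dice 0.9029, frac refined 1.00, total MACs 1.64e+08
evaluate_pipeline(m1, m2, test, grid, selection_config(threshold = 1))
#> eval_report (two_stage): 8 images, mean Dice 0.8380, frac refined 0.00, total MACs 9.66e+06
evaluate_pipeline(m1, m2, test, grid, selection_config(threshold = 0.85),
                  context = TRUE)
#> eval_report (two_stage): 8 images, mean Dice 0.8543, frac refined 0.05, total MACs 1.81e+07
```

Reading the numbers: refining every patch lifts mean Dice from 0.838
(coarse-only) to 0.903 at 17× the coarse cost; a stricter threshold
(`τ = 0.85`) buys roughly a quarter of that quality gain (0.854) for only
5% of patches refined — 1.9× the coarse cost. On these blurry desk-scale
coarse maps most patches exceed `0.25 · u_max`, so the reference operating
point `τ = 0.25` here refines everything.

Cost accounting in the style of a parameters/FLOPs table:

```r
op_count_table(c("tiny"), sizes = c(24L, 48L, 96L))
#>   architecture params macs_24x24 macs_48x48 macs_96x96
#> 1         tiny   4881    1290240    5160960   20643840
```

The ResNet-50-backed reference architectures (`fcn`, `deeplabv3`, `unet`,
`segnet`) are available for op accounting and contract checks; the
ResNet-50 encoder counts 23,508,032 (23.5 M) parameters and every
architecture's MAC count quadruples when the input side doubles.

## Command line

```sh
patchrefine synth        --out data --n 100 --size 96 --seed 0
patchrefine train-stage1 --manifest data/manifest.csv --out m1.json --size 96 --patches 16
patchrefine train-stage2 --manifest data/manifest.csv --m1 m1.json --out m2.json \
                         --strategy weighted --context
patchrefine predict      --image data/img_0001.pgm --out prob.pgm \
                         --m1 m1.json --m2 m2.json --threshold 0.25
patchrefine evaluate     --manifest data/manifest.csv --report report.json \
                         --m1 m1.json --m2 m2.json
patchrefine count-ops    --arch tiny,segnet --size 96,192
```

The wrapper script is installed at
`system.file("exec", "patchrefine", package = "patchrefine")`; every
command also works through `pr_cli(c("synth", ...))` from R. Images, masks
and 16-bit probability maps are read and written as netpbm PNM files;
datasets are described by CSV manifests with columns `image,mask,split`.

See the methods vignette (`vignettes/two-stage-refinement.Rmd`) for the
model assumptions, parameter choices, what the synthetic generator does and
does not emulate, and known limitations.
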