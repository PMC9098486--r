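# meanet

Binary segmentation of 2-D medical images with a multilayer edge-attention
encoder–decoder network (MEA-Net), implemented entirely in R with
Rcpp/RcppArmadillo numerical kernels. The package is aimed at researchers
who want a fully inspectable, dependency-light implementation of an
edge-aware segmentation network — every layer, the training loop and the
evaluation suite are plain R objects that can be probed, perturbed and
unit-tested — together with seeded synthetic phantoms so the whole system
runs end to end without any dataset download or GPU.

## The model

The network has three parts:

* **Feature encoder** — four stages E1..E4 of custom encoding blocks
  (default widths 64/128/256/512) separated by 2×2 max pooling. Each block
  runs a 3×3 convolution followed by asymmetric 3×1 and 1×3 convolutions
  (each with ReLU and batch normalisation) plus a 1×1-convolution residual
  path.
* **Edge module** — *edge feature extraction* (EFE) maps E1 and E2 into
  N = 16 channels with 3×3 convolutions, bilinearly upsamples the E2 branch
  by 2 and sums the branches into an attention stack
  `A = Conv3×3(X1) + U[Conv3×3(X2)]`. *Multilayer attention guidance*
  (MAG) multiplies each attention map into the shallow features and sums,
  `U_total = Σ_m (A_m ⊗ X1)`, gates channels with a squeeze-and-excitation
  block (`z_k = mean(u_k)`, `s = σ(W1 δ(W2 z))`, `Ũ = [s_1 u_1, …, s_C u_C]`),
  and branches into 1×1 convolutions producing decoder-bound edge features
  Y1 and a one-channel edge prediction Y2 for early supervision.
* **Feature decoder** — three cascaded decoding blocks. Each fuses
  low-level features (1×1 convolution) with high-level features that are
  1×1-convolved, bilinearly upsampled, pooled globally and squeezed through
  ReLU/sigmoid 1×1 layers into per-channel weights in [0, 1]. The last
  decoder output is combined with Y1 and a final convolution plus sigmoid
  yields the segmentation probability map.

Training minimises the joint objective

    L_total = α · L_Dice(edge head) + (1 − α) · L_BCE(segmentation head),  α = 0.3

with Adam (lr 2e−3, betas (0.5, 0.999), batch size 4). Evaluation reports
per-image accuracy, sensitivity, Dice, pixelwise ROC AUC and the boundary
F1 (BF) score, aggregated as mean ± standard deviation.

Every ablation of the edge module is reachable through configuration:
`use_efe`, `use_mag`, `efe_stages` (any subset of E1..E4, deeper stages
upsampled back to E1 resolution) and the Y1 fusion mode.

## Worked example

Train the full default network to overfit eight synthetic 64×64 blob
phantoms (a compact foreground object on a cluttered background), then
evaluate on the same images:

```r
library(meanet)

phantoms <- lapply(1:8, function(k)
  generate_phantom(phantom_spec("blob", c(64, 64), seed = k)))

cfg <- train_config(augment_ops = character(0), eval_every = 3,
                    max_epochs = 100, global_seed = 42)
fit <- train_meanet(phantoms, cfg, max_steps = 200, stop_dice = 0.95,
                    verbose = TRUE)
#> epoch 3 step 6 loss 0.2393 val_dice 0.4427
#> epoch 6 step 12 loss 0.1740 val_dice 0.6678
#> epoch 9 step 18 loss 0.1354 val_dice 0.9461
#> epoch 12 step 24 loss 0.0988 val_dice 0.9713

evaluate_meanet(fit$best_model, phantoms)
#> Segmentation metrics over 8 images (threshold 0.50)
#>   accuracy     0.9832 ± 0.0054
#>   sensitivity  1.0000 ± 0.0000
#>   dice         0.9713 ± 0.0090
#>   auc          1.0000 ± 0.0000
#>   bf           0.4977 ± 0.0560
```

The monitored Dice crosses 0.95 after 24 optimiser steps; training stops
early. Accuracy, Dice and AUC approach 1 as the network memorises the
eight masks, while the BF score stays lower because its default matching
tolerance (0.75 % of the image diagonal, well under one pixel at 64×64)
only credits boundary points that are almost exactly right.

Other entry points: `meanet_forward()` (probability maps for new images),
`predict_meanet()` (PNG output), `make_splits()` (seeded 8:1:1 or k-fold
splits), `write_dataset()`/`read_dataset()` (PNG + JSON manifest), and the
block-level functions (`encoding_block_forward()`, `efe_forward()`,
`mag_aggregate()`, `se_forward()`, `mag_forward()`,
`decoding_block_forward()`) for inspecting individual components. A thin
command-line wrapper with `synth`/`split`/`train`/`eval`/`predict`
subcommands is installed under `inst/cli/meanet`.

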