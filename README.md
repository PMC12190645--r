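# cropdx

Crop-disease diagnosis from leaf images, as a single reproducible R
pipeline:

1. **Denoising** — adaptive anisotropic diffusion: explicit Perona–Malik
   iteration `I ← I + λΔt Σ_d c_d ∇_d I` whose conductance combines a
   contrast-threshold edge-stopping term `1/(1 + (‖∇I‖/k)²)` (k = 30 on
   the 0–255 scale) with a local-variance modulation, so homogeneous
   regions smooth while lesion edges survive.
2. **Segmentation** — a nested U-Net++ encoder–decoder (dense skip
   lattice, conv–batchnorm–ReLU blocks) fused with fuzzy logic: Gaussian
   class memberships `μ_A(x) = exp(−(x−c_A)²/2σ_A²)` fitted from
   training histograms, Mamdani min-implication rules at the top-row skip
   junctions and the decision stage, and centroid defuzzification
   `COA = Σ x·μ(x) / Σ μ(x)` over the 0–255 intensity domain.
3. **Feature selection** — convolutional summary features (3×3 kernels,
   stride 1, global average pooling) filtered by a gorilla/remora
   population metaheuristic: gorilla steps
   `X_new = X_best + s·(X_best − X_current)`, remora attachment steps
   `X_host + f(d)·(X_best − X_host)`, and the wrapper fitness
   `J(F) = α·Accuracy(F) − β·Redundancy(F)`.
4. **Classification** — a graph-convolutional LeNet-style head: nodes are
   selected features, edges are thresholded profile correlations,
   propagation is `H^(l+1) = ReLU(D^(−1/2) A′ D^(−1/2) H^(l) W^(l))`,
   followed by a global max pool and a softmax layer.

Every stage is testable without external data through a parametric leaf
phantom generator with exact ground-truth masks.  The neural networks are
implemented in-package on base matrix algebra with hand-derived backward
passes (verified by finite-difference gradient checks) and an in-package
Adam optimizer.

## Worked example

```r
library(cropdx)

spec <- phantom_spec(image_size = 32, n_classes = 3, noise_sigma = 0.02,
                     lesion_count_range = c(2L, 2L),
                     lesion_radius_range = c(4, 5))
ds <- generate_dataset(spec, n_per_class = 20, seed = 31)

cfg <- pipeline_config(
  target_size = 32L, n_classes = 3L,
  unet = unetpp_config(depth = 3, filters = c(8L, 16L, 32L),
                       in_channels = 1, n_classes = 5L, seed = 42),
  mgra = mgra_config(population = 10, generations = 15, seed = 42),
  n_kernels = 32L,
  seg_train = list(epochs = 30, batch_size = 4),
  glnp_train = list(epochs = 30, batch_size = 4),
  seed = 42)

run <- run_pipeline(ds, cfg)
run
#> <cropdx_run> 14 selected features; test metrics:
#>   accuracy precision recall  f1 auc
#> 1      100       100    100 100 100

head(run$reports$denoising, 3)
#>   image_id noise_level_before noise_level_after edge_preservation_index ...
#> 1    Img01         0.01971375       0.002288116               0.9939094
#> 2    Img02         0.01928612       0.002125413               0.9932071
#> 3    Img03         0.01764963       0.001912661               0.9918355

run$reports$selection
#>   dataset_id initial_feature_count selected_feature_count selection_ratio
#> 1      train                    32                     14            43.8
```

Reading the output: the held-out fifth of the 60 phantoms is classified
perfectly (all five rates are percentages); diffusion cut the per-image
noise estimate roughly tenfold while the edge-preservation index stayed
above 0.99 (here computed between the noisy input and its denoised
output); and the selector kept 14 of 32 convolutional features (43.8%).
`run$reports$segmentation` and `run$reports$classification` carry the
per-image segmentation quality (accuracy, mean IoU, fuzzy overlap) and
per-image predictions with confidences.

Fitted objects follow broom conventions — `tidy()` on an `mgra_result`
gives the best-fitness history, `glance()` on a run gives the one-row
metric summary — and `autoplot()` methods plot segmentation maps,
training curves, selection histories and confusion matrices.

A thin command-line front end is installed with the package
(`system.file("cli", "cropdx.R", package = "cropdx")`) with verbs
`phantom`, `denoise`, `run` and `select`.

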