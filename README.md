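# stemleaf

Stem/leaf semantic segmentation of 3-D crop point clouds across the full
growth cycle, with an adaptive two-stage down-sampler, a geometry-aware
multi-scale point-transformer, and a keypoint-retention benchmark — all
runnable at desk scale on one CPU core against a bundled synthetic plant
generator.

## Who this is for

Plant-phenotyping researchers and method developers who work with
organ-labelled crop point clouds (multi-view reconstruction, LiDAR,
structured light) and need (a) a down-sampling budget that adapts to plant
structure instead of a fixed ratio, (b) a trainable stem/leaf segmentation
network whose components can be ablated and studied, and (c) reproducible,
self-contained benchmarks that do not depend on multi-gigabyte external
scans.

## The method in brief

**Adaptive sampling.** A cloud is thinned uniformly to 10 %, then
farthest-point sampling runs on that subset at the rate

  r_FPS = r_base · (w_v + λ · w_d),  w_v = 1/(1 + CV_v),  w_d = CV_d/(CV_v + CV_d)

where CV_v is the coefficient of variation of per-voxel occupancy (5 cm
voxels) and CV_d the CV of kNN local densities ρ_i = k / Σ‖p_i − p_j‖²
(k = 50). The overall retained fraction is clamped to [2 %, 8 %]. Uneven
global occupancy lowers the budget; strong local crowding (overlapping
foliage) raises it.

**Segmentation.** An encoder–decoder point transformer: per-point messages
φ_s([f_j − f_i; ψ_ij]) over ball neighbourhoods at radii 0.05/0.10/0.15 of
plant height (ψ_ij a learned embedding of [Δp_ij; ‖Δp_ij‖]), geometry-aware
attention a_ij = softmax_j(−d_ij/σ) mixing raw neighbour features, linear
fusion, FPS + max-pool transitions down, inverse-distance-squared
interpolation up, and a fully connected head. Metrics are one-vs-rest
IoU = TP/(TP+FP+FN) and Acc = (TP+TN)/N per class, with mIoU/mAcc their
two-class means. Training is AdamW (lr 0.003, batch 2) with weighted
cross-entropy, cosine decay and early stopping — backed by the package's
own reverse-mode tape, so no deep-learning framework is required.

**Sampler benchmark.** Intrinsic-shape-signature keypoints (eigenvalue-ratio
tests on local covariance, non-maximum suppression) are extracted once; each
sampler is scored by the fraction of keypoints with a sampled point within
ε (default 2× mean nearest-neighbour spacing), at a matched point budget.

## Worked example

```r
library(stemleaf)

cl <- generate_plant(plant_spec(crop = "soybean_like", stage = 9, seed = 42))
cl
#> # A point cloud 'soybean_like_c1_s09_seed42' with 12463 points (labelled)

res <- dmss_sample(cl, dmss_params(seed = 42))
res
#> Dynamic multi-stage sampling result
#>   N = 12463 -> stage 1: 1246 -> final: 456 (overall 3.66%)
#>   CV_v = 1.0817 (w_v = 0.4804)  CV_d = 1.1014 (w_d = 0.5045)
#>   C_joint = 1.0916  r_fps = 0.3663
```

The reproductive-stage plant shows strong occupancy dispersion (CV_v ≈ 1.08,
so w_v ≈ 0.48) and comparable local-density dispersion from its overlapped
canopy (CV_d ≈ 1.10, w_d ≈ 0.50), giving an FPS rate of 0.37 on the thinned
subset — an overall 3.66 % budget, inside the [2 %, 8 %] clamp. A stage-1
seedling under the same parameters lands nearer 3.3 %: denser sampling goes
to the structurally complex plant. `tidy(res)` returns the same numbers as
a one-row tibble; `cl[res$final_indices, ]` is the sampled cloud.

Training and evaluating a desk-scale model:

```r
train <- tibble::tibble(cloud = lapply(1:10, function(i) {
  p <- generate_plant(plant_spec(stage = 2, seed = i))
  p[farthest_point_sample(cloud_coords(p), 220, seed = i), ]
}))
cfg <- seg_config(channels = c(16, 32), n_stages = 2,
                  max_neighbors = 12, knn_k_attention = 8)
fit <- train_model(build_model(cfg, seed = 1), train,
                   config = train_config(max_epochs = 30), augment = NULL)
evaluate_model(fit, train)$aggregate   # per-class Acc/IoU, mAcc, mIoU in %
```

A command-line interface wraps the same functions
(`inst/exec/stemleaf simulate | sample | benchmark | train | segment | eval`).

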