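---
title: "Adaptive sampling and geometry-aware segmentation of crop point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive sampling and geometry-aware segmentation of crop point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemleaf)
```

## The problem

Organ-level semantic segmentation of 3-D crop point clouds — labelling every
point as *leaf* or *stem* — is a core step in plant phenotyping: stem height,
leaf area and canopy architecture all derive from it. Clouds reconstructed
from multi-view imaging or LiDAR are large (10⁵–10⁷ points), strongly
non-uniform in density (overlapping foliage reconstructs much denser than
slender stems), and change drastically in size and complexity between a
seedling and a mature plant. `stemleaf` provides the full stack this task
needs: an adaptive down-sampler whose budget responds to structural
complexity, a geometry-aware multi-scale point-transformer trained on CPU at
desk scale, a keypoint-retention benchmark for comparing samplers, metrics,
augmentation, and a procedural generator of labelled plant clouds for
controlled experiments.

Clouds are ordinary tibbles with columns `x`, `y`, `z` (metres) and an
optional integer `label` (0 = leaf, 1 = stem), so every step composes with
dplyr and the pipe. All coordinates are metres throughout; "5 cm voxels"
means `voxel_edge = 0.05`.

## The adaptive two-stage sampler

Fixed-ratio down-sampling treats a 15 cm seedling and a 120 cm closed canopy
alike. The dynamic multi-stage strategy conditions the budget on two
complementary dispersion measures, both plain coefficients of variation:

* **Voxel-occupancy variation.** The cloud is voxelised on a 5 cm grid
  anchored at the bounding-box minimum; over *occupied* voxels with counts
  \(N_v\), \(CV_v = \sigma_N / \mu_N\) and the sparsity weight is
  \(w_v = 1/(1 + CV_v)\). Uneven occupancy (high \(CV_v\)) lowers the budget
  through \(w_v\), protecting sparse but structurally important regions from
  being the only thing sampled.
* **Local-density variation.** With \(\rho_i = k \big/ \sum_{j \in kNN(i)}
  \lVert p_i - p_j \rVert^2\) (k = 50), \(CV_d = \sigma_\rho / \mu_\rho\)
  and the complexity weight is \(w_d = CV_d / (CV_v + CV_d)\). Strong local
  crowding — overlapping leaves, self-occlusion — raises the budget.

The sampler first thins uniformly at random to 10 % of the points, then runs
farthest-point sampling (FPS) on that subset at the rate
\(r_{FPS} = r_{base}\,(w_v + \lambda\, w_d)\); the *overall* retained
fraction relative to the original cloud is clamped to [2 %, 8 %]. A joint
diagnostic \(C_{joint} = \lambda\, CV_v + (1-\lambda)\, CV_d\) is reported
alongside but does not drive the rate: only the weight rule is tied to
\(r_{FPS}\), and inventing a second mapping from \(C_{joint}\) to a ratio
would duplicate the mechanism.

Numerical and design choices:

* Statistics are computed on the **original** cloud, not the thinned subset:
  they are then independent of the stage-1 seed.
* **Population** standard deviations, and occupied voxels only — including
  empty voxels would make \(CV_v\) depend on bounding-box padding.
* \(r_{base} = 0.5\) and \(\lambda = 0.5\) by default, placing a
  moderately complex cloud near the middle of the clamp (≈ 5 % overall);
  both are configuration fields.
* The clamp acts on the overall fraction, realised by clamping the FPS-stage
  rate to `[clamp_lo, clamp_hi] / stage1_ratio`.
* The density reading `k / sum(d²)` (larger = denser) is the default; the
  reciprocal reading is available via `density_reciprocal`. Their CVs agree
  to first order but are **not** identical — a point worth stating because
  it is easy to assume CV is invariant under reciprocals; it is only
  invariant under rescaling.
* FPS is exact and deterministic: the start index comes from the seed (or a
  caller-supplied start), each step maximises the minimum distance to the
  selected set, and ties break to the lowest index. The test suite holds it
  to index-for-index agreement with a brute-force oracle.

## The segmentation network

The network is an encoder–decoder over point sets, built from four
operators.

**Multi-scale aggregation.** Each point gets three ball neighbourhoods with
radii 0.05, 0.10, 0.15 *of the plant height* (the vertical bounding-box
extent). Scaling radii rather than coordinates keeps I/O in metres and makes
neighbour sets invariant under uniform rescaling of a plant. The message
from neighbour *j* to centre *i* at scale *s* is
\(\phi_s([f_j - f_i;\, \psi_{ij}])\), where \(\psi_{ij}\) is a two-layer
perceptron of \([\Delta p_{ij}; \lVert \Delta p_{ij} \rVert]\) — a learned
positional embedding that depends only on relative geometry, hence is
translation-invariant by construction. Messages are combined by an
attention-weighted sum and the three scales are concatenated.

**Geometry-aware attention.** Neighbour weights are
\(a_{ij} = \mathrm{softmax}_j(-d_{ij}/\sigma)\): nearer points receive
larger prior weights, and the attended feature is \(\sum_j a_{ij} f_j\) on
the raw neighbour features (following the defining equation literally, not
on value-transformed features — this keeps the ablation comparison against
the q/k/v baseline meaningful). With `sigma_mode = "radius"` (default)
\(\sigma\) equals the effective radius of the neighbourhood's scale, making
the weights scale-free; a fixed \(\sigma\) in metres is the alternative.
These same distance-kernel weights serve as the "Agg" of the multi-scale
messages — the two places share one parameterisation rather than
introducing a second, unstated one.

**Transitions.** TransitionDown selects an FPS support (ratio 0.25) and
max-pools linear+ReLU-transformed features over each support point's ball;
TransitionUp interpolates coarse features to fine points by inverse squared
distance over the 3 nearest coarse points (weights \(\propto 1/(d^2 +
10^{-8})\), normalised), so coincident points recover their coarse feature.
Effective radii grow by \(1/\sqrt{\text{down\_ratio}}\) per level, keeping
the expected neighbour count roughly constant as the support thins (points
live on surfaces, so spacing grows with the square root of the thinning
factor). The decoder concatenates up-sampled features with the encoder skip
at each level, applies a linear map, then geometry-aware attention; a
two-layer fully connected head emits per-point class scores.

**Determinism and permutation stability.** The internal FPS starts at the
lexicographically smallest point, so inference does not depend on point
order; continuous coordinates make distance ties measure-zero. Input
features are centred, height-normalised coordinates, so forward scores are
translation-invariant to floating-point accuracy.

**Ablations.** `no_multiscale` keeps only the mid-radius scale;
`no_geometry_attention` removes the attention branch and replaces
attention-weighted aggregation with plain means; `baseline_pt` replaces each
encoder block with the plain q/k/v self-attention layer
(\(\hat{x} = \mathrm{softmax}(q k^{\top}) v\) over the kNN neighbourhood).
Each ablation strictly reduces the trainable parameter count, which the
tests assert structurally.

**Training.** No automatic-differentiation framework is assumed: the
package carries a minimal reverse-mode tape over the dozen matrix primitives
the network uses, verified against central finite differences. The loss is
weighted cross-entropy (inverse-frequency weights by default — stems are
the minority class and otherwise dominate the error budget), optimised with
AdamW at initial learning rate 0.003, batch size 2, cosine annealing
(step decay optional), and early stopping with patience 20 and min-delta
1e-4 on the raw validation loss ("no significant improvement" is read as a
min-delta rule, not a statistical test). Because every augmentation below
preserves neighbour sets and attention weights, each cloud's neighbourhood
pyramid is precomputed once and reused for all epochs; only the pair offsets
feeding \(\psi_{ij}\) are recomputed. Mixed precision is not implemented —
it is an accelerator-efficiency device with no meaning for double-precision
CPU linear algebra at these sizes.

## Augmentation

Three label-preserving transforms emulate field-acquisition variability:
a rigid uniform shift within ±0.5 m per axis (equipment positioning), an
isotropic rescale by a factor in [0.8, 1.2] about the centroid (the 15–120
cm growth range), and a flip through the XZ plane with probability ½
(one-sided scanning). Shift is an isometry; the flip is an isometry and an
involution; rescaling commutes with the height-normalised radii. All three
therefore leave the cached geometry valid, which the invariance tests check
directly.

## Keypoint-retention benchmark

Samplers are compared by how well they preserve intrinsic shape signature
(ISS) keypoints: for each point the eigenvalues \(\lambda_1 \ge \lambda_2
\ge \lambda_3\) of the unweighted covariance of its salient-radius
neighbourhood are computed; candidates need \(\lambda_2/\lambda_1 <
\gamma_{21}\) and \(\lambda_3/\lambda_2 < \gamma_{32}\) (both 0.975) and at
least 5 neighbours; non-maximum suppression keeps local maxima of
\(\lambda_3\). Radii default to 6× (saliency) and 4× (suppression) the mean
nearest-neighbour spacing — the customary ISS setting when none is
prescribed. A keypoint counts as *retained* if some sampled point lies
within ε of it (default: 2× mean nearest-neighbour spacing). A strict
index-membership reading would make retention collapse toward the sampling
ratio itself at 2–8 % budgets, which is why coverage within a tolerance is
the implemented definition. The benchmark runs random sampling, plain FPS
and the adaptive sampler at the *matched* budget the adaptive sampler
realises, reporting mean ± sd retention over seeds; wall-clock time is
recorded as information only and never asserted.

## The synthetic plant generator

The generator replaces external scan datasets at desk scale. Stems are
points on tapering tubes around drifting vertical splines (plus
stage-dependent branches); leaves are drooping elliptical patches —
trifoliate groups for the soybean analogue, long narrow blades for maize,
compact clusters for tomato — attached along the stem in a spiral
phyllotaxy. Stage (1–12 for soybean; a day index for maize/tomato) drives
height linearly from 0.15 m to 1.20 m, leaf count, occlusion and density
structure. Points are allocated in proportion to true surface area (a
uniform scan), with two stage-dependent departures: upper-canopy leaves
carry a modest budget boost, and a growing fraction of upper-leaf points is
drawn from tight micro-clusters on the leaf surface. The second mechanism
is deliberate: overlapping foliage in multi-view reconstruction produces
*sub-voxel* densification, which raises the local-density CV sharply while
leaving 5 cm voxel occupancy almost unchanged — exactly the signature the
adaptive rule keys on. Occlusion removes a seeded fraction of points hidden
from a random viewpoint (angular-bin hidden-point test), and Gaussian noise
(1.5 mm) perturbs coordinates. Cultivars differ by systematic height and
leaf-size offsets, mirroring a multi-cultivar field design; splits hold out
whole cultivars (or whole plants for the day-indexed crops).

What the generator does *not* emulate: photorealistic leaf texture, true
L-system branching, colour/multispectral channels, sensor-specific noise,
or the sub-millimetre resolution of real multi-view rigs (budgets here are
roughly 600–25 000 points per plant). Passing tests therefore demonstrate
that the algorithms behave as designed under the stated statistical
structure — stage-monotone complexity, class imbalance, density contrast —
not that any particular accuracy carries over to a specific real scanner.

## Problem sizes and budgets

The test and acceptance workloads are deliberately small so the whole stack
runs on one CPU core in minutes: desk-scale training uses ten stage-2
plants thinned to 220 points each (plus four validation plants), a
two-stage network with 16/32 channels, and at most 200 epochs; the sampler
benchmark uses twenty stage-8–12 plants at the generator's default density
(roughly 9–25 k points); formula-level checks run on clouds of up to a few
thousand points against brute-force oracles. These sizes are the package's
chosen experimental conditions, stated here so results are read at the
scale they were produced.

## Known limitations

* The trainer is exact but plain R; it is intended for desk-scale
  experiments and method study, not for training on full-resolution scans.
* ISS parameters are heuristics tied to nearest-neighbour spacing; clouds
  with highly anisotropic sampling may need explicit radii.
* The hidden-point occlusion model is an angular-bin approximation, not a
  true visibility computation.
* `overall_ratio` can sit just outside the clamp by one point because
  point counts are integers.
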