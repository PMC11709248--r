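---
title: "Identifying ligands in density maps: models, normalization and design choices"
author: "ligandblob"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying ligands in density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Small-molecule ligands appear in experimental density maps as connected
regions ("blobs") of positive density that the macromolecular model does not
explain. In X-ray crystallography the standard object is the Fo&minus;Fc
difference map, conventionally contoured at 2.8&sigma;; in cryoEM the
analogue is a real-space difference map between the ligand-free model and
the reconstruction. `ligandblob` implements an end-to-end pipeline that
turns such maps into classified ligand identities: blob extraction on a
canonical 0.2&nbsp;&Aring; grid, cryoEM-specific value normalization,
conversion to point clouds, capped point sampling, and classification into
*ligand groups* with point-cloud neural networks, together with the
evaluation protocol (deposit-grouped splits, five metrics) needed to assess
such classifiers honestly.

A ligand *group* rather than a single chemical identity is the prediction
target because several chemistries are indistinguishable by shape of their
density alone. Two ligands share a group when they agree on heavy-atom
count, ring count, heavy-atom graph connectivity, chirality and element
composition; groups below a minimum number of observed blob instances
(default 100) are collapsed into a catch-all "rare" class.

## CryoEM map normalization

X-ray difference maps are near-normal in their voxel values, so a fixed
2.8&sigma; cutoff transfers across deposits. CryoEM maps are not: solvent
masking and arbitrary box padding put a large spike of exact and near
zeros into the histogram (zero inflation), and sharpening conventions vary
between labs, so neither a fixed absolute nor a fixed sigma cutoff is
comparable across entries. `normalizeCryoemMap()` therefore applies three
steps:

1. **Zero-inflation trimming** (`trimZeroInflation`): all voxel values
   within &plusmn;0.5&nbsp;SD of the median (both computed on the *entire*
   map, zeros included) are discarded. The spike sits at the median of a
   masked map, so this removes it while keeping both value tails.
2. **Quantile thresholding** (`quantileThreshold`): the cutoff is the
   empirical quantile of the trimmed sample at probability
   &Phi;(2.8)&nbsp;&asymp;&nbsp;0.9974449, i.e. the probability mass a
   2.8&sigma; contour would cut from a normal distribution. The constant is
   computed as `pnorm(2.8)` at machine precision; 0.9974 is its 4-digit
   rounding. The quantile estimator interpolates linearly between order
   statistics (R type 7), matching the naive sort-based definition.
3. **Value calibration** (`rescaleToCalibration`): after zeroing voxels
   below the cutoff, values are rescaled multiplicatively so the lowest
   surviving value equals a per-resolution target: the mean lowest nonzero
   value of X-ray blobs at that resolution, looked up in a
   `CalibrationTable` with 0.1&nbsp;&Aring; bins, nearest-bin lookup and
   edge clamping. No published table values exist, so the package ships a
   synthetic, monotone table generator (`makeCalibrationTable`) for testing;
   users with X-ray data can supply their own TSV.

The composition is scale invariant (median, SD and quantiles are
equivariant under positive scaling, and the final rescale removes the
factor), which the tests assert exactly. Trimming statistics are computed
once, in a single pass; the wording of the procedure is single-pass and we
found no reason to iterate.

## Blob extraction and quality filters

`connectedComponents()` labels nonzero voxels under 6-, 18- or
26-connectivity (default 26: the most permissive choice, which avoids
splitting ligands connected through thin density bridges at
0.2&nbsp;&Aring; sampling; the convention is not dictated by the method
itself). Volumes are nonzero-voxel counts times the voxel volume
(0.008&nbsp;&Aring;&sup3; at canonical spacing). The ligand quality filters
follow the printed inequalities exactly, including their boundary
semantics: X-ray ligands are *rejected* when resolution&nbsp;&gt;&nbsp;4.0,
RSCC&nbsp;&lt;&nbsp;0.6, RSZO&nbsp;&lt;&nbsp;1.0, RSZD&nbsp;&ge;&nbsp;6.0,
R&nbsp;&gt;&nbsp;0.3 or occupancy&nbsp;&lt;&nbsp;0.3; cryoEM ligands are
*kept* when Q-score&nbsp;&ge;&nbsp;0.6 ("0.6 or better", inclusive) and
volume&nbsp;&gt;&nbsp;2.14&nbsp;&Aring;&sup3; (strict). Blob-to-ligand
assignment uses a 2.0&nbsp;&Aring; radius from any non-hydrogen atom to the
nearest nonzero voxel center, roughly a covalent bond length plus half a
voxel diagonal.

## Point sampling

A blob grid becomes a point cloud with one point per nonzero voxel at the
voxel center, carrying the voxel's density. Four strategies cap a cloud at
`max_p` (default 2000) points:

- **uniform** (`sampleUniformMax`, the preferred strategy): a divisor N
  cuts the grid into N&sup3; equal blocks (zero-padded; e.g. a
  (20,16,10) grid at N&nbsp;=&nbsp;2 gives 8 blocks of shape (10,8,5));
  N starts at 1 and is incremented while the next N keeps the occupied
  block count within budget. One point per occupied block survives: the
  maximum-density voxel, with coordinates and density unchanged. Ties on
  the maximum are broken towards the lowest (z,&nbsp;y,&nbsp;x) index, a
  determinism choice of this implementation. The literal incremental stop
  rule is retained even though occupancy can in principle be non-monotone
  in N for sparse masks.
- **random**: uniform without replacement, seeded.
- **surface**: uniform over the shell of nonzero voxels with at least one
  zero or out-of-bounds face neighbor (6-connectivity is the strictest
  notion of "outer shell").
- **clustering**: k-means on coordinates with k&nbsp;=&nbsp;`max_p`,
  seeded k-means++ initialization and at most 50 Lloyd iterations;
  centroids become the points. Because downstream models need a density
  per point, each centroid carries the density of its nearest original
  point, keeping values at the original scale like the uniform strategy.

## Classifiers

Two trainable architectures are provided, both built on a small
reverse-mode autodiff tape over dense matrices written for this package
(the R ecosystem here has no deep-learning framework, and the classifiers
are the package's core, so they are implemented from first principles;
gradients are verified against finite differences in the tests).

**Rotation-invariant point convolutions** (`architecture = "riconvpp"`).
Each point receives a local reference axis (LRA): the smallest-eigenvalue
eigenvector of its k-neighborhood covariance (k = `neighborhoodK`, default
16), sign-fixed towards the cloud centroid so the axis is a deterministic
function of the geometry. All neighborhood features are distances and dot
products of LRAs, neighbor offsets and centroid directions - quantities
exactly preserved under rigid rotation - so the network's output is
rotation invariant by construction, not approximately. Five stacked
invariant convolution layers (shared linear map over each point's
neighbors, normalization, ReLU, max over the neighborhood) are followed by
symmetric global pooling (max and mean over points) and two fully
connected layers with a softmax. Normalization is computed per cloud
(instance-style batch normalization): this keeps single-cloud inference
numerically identical to batched training, which matters because training
batches stack same-sized clouds into one tape for BLAS efficiency.

**Sparse-voxel feature pyramid** (`architecture = "minkloc"`). The cloud
is quantized into sparse voxels at `quantizationSize` (default
0.2&nbsp;&Aring;, one canonical voxel; duplicate points keep their maximum
density) with density as the single input feature. A bottom-up pathway of
three 3&times;3&times;3 sparse convolution blocks with increasing receptive
fields (stride-2 pooling between levels; widths 32/64/128), each with
normalization, ReLU and an Efficient Channel Attention gate (kernel 3),
feeds a top-down pathway that projects coarser maps back onto finer
coordinates (parent-lookup upsampling plus 1&times;1 projections standing
in for transposed convolutions on a sparse grid). The fused local features
are aggregated by NetVLAD (default 32 clusters): soft-assignment of each
local feature to learned clusters, accumulation of residuals against
cluster centers, intra- and global L2 normalization, then a linear
classifier. The network is equivariant to translations aligned with the
coarsest stride (4 voxels) and, like the invariant network, exactly
invariant to point order.

The hidden widths, neighborhood size and cluster counts are configuration
defaults of this implementation, exposed in `modelConfig()`; the cited
architecture families leave them to the practitioner and we make no claim
that they match any published training run. The final classification layer
is zero-initialized so an untrained model outputs exactly uniform scores.

**Training** (`trainModel`) minimizes cross-entropy with Adam, accumulating
gradients over `gradAccumulationBatches` clouds per step. Class imbalance
can be handled by per-epoch oversampling (duplicate minority examples up to
the majority count) or undersampling (cap majority classes at the minority
count). A stratified fraction (default 20%) of the input is held out for
per-epoch validation accuracy. All randomness (initialization, shuffling,
resampling) flows from explicit seeds, and training is bit-reproducible for
a fixed seed on a fixed BLAS.

## Evaluation protocol

Deposits (PDB entries) are the unit of data splitting: all ligands of a
deposit land on the same side of every split, so no structure contributes
to both training and testing. `depositStratifiedSplit()` assigns deposits
greedily, largest first in seeded random order, to keep each group's train
fraction near 70%, then carves 25% of the training examples (again at
deposit granularity) into a validation set. `stratifiedKfold()` distributes
deposits over k folds (default 3) minimizing per-group imbalance.

`computeMetrics()` reports classification accuracy, top-10 accuracy, mean
correct prediction rank, Brier score and macro-averaged recall. The Brier
score follows the correct-class reading - mean((1&nbsp;&minus;&nbsp;p_true)&sup2;) -
with the multiclass sum-over-classes variant available behind
`multiclassBrier = TRUE`. Argmax and rank ties are broken towards the
smallest class index everywhere, one consistent rule across accuracy and
rank. Classes absent from the test truths are excluded from the macro
recall mean rather than counted as zero, so folds lacking rare classes are
not penalized; both tie-break and exclusion are implementation policy,
stated here because the protocol itself does not fix them.

## Synthetic data: what it does and does not show

All tests run on synthetic data generated in code:

- `renderPseudoLigand()` renders sums of isotropic Gaussians (width
  &sigma;&nbsp;=&nbsp;0.425&nbsp;&times;&nbsp;resolution, chosen so the
  Gaussian FWHM matches the nominal resolution) on the canonical grid,
  with contributions below 0.1% of the peak truncated to exact zero so
  blobs have compact support.
- `makeZeroInflatedMap()` emulates a solvent-masked cryoEM difference map:
  Gaussian background, an exact fraction of voxels set to zero, and
  pseudo-ligands at known positions. Masked voxels are drawn outside blob
  support - solvent masks do not cut through the particle - which makes the
  zero fraction exact and the ground truth clean. Ground-truth masks are
  defined at 1% of each blob's peak, an arbitrary but fixed convention
  needed for recovery scoring.
- `makeShapeDataset()` provides the 5-class training stand-in (line, ring,
  tetrahedron, T-shape, helix; random rigid rotations, 0.15&nbsp;&Aring;
  jitter, near-constant densities). The classes are separable by
  rotation-invariant shape statistics by construction - a nearest-centroid
  classifier on covariance eigenvalues and radial moments exceeds 95%
  accuracy - so passing the training smoke test demonstrates that the
  architectures, gradients and training loop work, *not* that they reach
  any particular accuracy on real 219-group ligand data, which requires
  PDB-scale training.

**Recovery scoring.** The end-to-end test embeds pseudo-ligands at
signal-to-noise ratio (peak density over background SD) of at least 5,
normalizes, extracts components and requires that, for every ground-truth
blob, the best-matching component lies at least 90% inside the truth mask
with its densest voxel inside the mask. The cutoff is deliberately
conservative - a 2.8&sigma;-equivalent quantile keeps only the strong core
of a blob - so recovery is scored as the component being a pure core subset
of the true density; covering 90% of a 1%-of-peak mask would instead
require peaks hundreds of times the background SD and would not test the
thresholding regime the method actually uses.

## Numerical choices and degenerate inputs

- Voxel convention: voxel i spans [origin&nbsp;+&nbsp;i&middot;s,
  origin&nbsp;+&nbsp;(i+1)&middot;s) and carries the density at its center;
  map nodes coincide with voxel centers after resampling, so resampling a
  map already at target spacing is the identity on values.
- Trilinear interpolation (exact on constant and linear fields) is used
  for resampling; the choice is ours - the procedure this implements does
  not state an interpolation scheme. Interpolation runs in fractional
  coordinates via the cell matrix, so non-orthorhombic crystallographic
  cells are handled.
- Constant maps, all-zero grids, empty clouds and single-class training
  sets raise typed errors (`ligandblob_degenerate_error`,
  `ligandblob_validation_error`) rather than producing silent nonsense.
- Unparseable SMILES raise a chemistry-parse error; label-space builders
  route such ligands to the rare class so blob-level datasets stay total.
- "Connectivity" in the grouping key is read strictly as graph isomorphism
  (canonical form of the stereo-stripped molecule); a coarser invariant
  (e.g. degree sequences) would merge more ligands and was rejected as a
  weaker reading.

## Problem sizes used in the checks

The shipped checks run at desk scale on one CPU: training smoke tests use
the 5-class shape dataset at its defaults (200 clouds per class, 48 points
per cloud) for up to 8 epochs with the rotation-invariant architecture;
gradient checks and invariance loops use reduced widths (8-16 channels)
and 20-50-point clouds; recovery runs on a 64&sup3; map with two ligands;
oracle-equivalence suites use grids up to 14&sup3; against brute-force
flood fill and exhaustive divisor search. These sizes were chosen so the
whole suite completes in well under half an hour while still exercising
every code path; none of the scientific constants (2.8&sigma;, &Phi;(2.8),
&plusmn;0.5&nbsp;SD trimming, the 2.14&nbsp;&Aring;&sup3; volume bound, the
quality-filter boundaries, max_p&nbsp;=&nbsp;2000, the 100-instance group
minimum) is altered for speed.

## Known limitations

- The published 219-group label space and headline accuracies require the
  full PDB snapshot and GPU training; this package reproduces the method,
  its contracts and its desk-scale behavior, not those numbers.
- The calibration table shipped for tests is synthetic; real use requires
  a table derived from X-ray blobs.
- Sparse convolutions are realized with dense matrix algebra over gathered
  neighbor lists; this is exact but not tuned for clouds near the
  2000-point budget with large channel widths on weak hardware.
- Q-score, RSCC, RSZO and RSZD are consumed as inputs; computing them from
  maps and models is out of scope, as are FDR thresholding and
  structure-factor synthesis.
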