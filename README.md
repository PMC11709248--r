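# ligandblob

Identification of small-molecule ligands in experimental density maps —
crystallographic Fo−Fc difference maps and cryoEM difference maps — by
treating density blobs as 3D point clouds and classifying them with
trainable point-cloud networks.

## Who this is for

Structural biologists and methods developers who need to (a) extract and
standardize ligand-sized density blobs from MRC/CCP4 maps, (b) bring cryoEM
maps onto a calibration where X-ray-trained models apply, and (c) train and
evaluate ligand-group classifiers with leakage-free protocols.

## The method

Ligands are located as connected positive-density regions of the
difference map. X-ray maps are contoured at the conventional 2.8σ
isosurface on a 0.2 Å grid. CryoEM maps, whose voxel histograms are
zero-inflated by solvent masking and differ in sharpening conventions, are
normalized in three steps before contouring:

1. discard voxel values within ±0.5 SD of the median of the whole map
   (removes the zero spike),
2. threshold at the empirical quantile of the remaining values at
   probability Φ(2.8) ≈ 0.9974 (the mass a 2.8σ contour cuts from a
   normal), and
3. rescale values multiplicatively so the lowest surviving value matches
   the mean lowest nonzero value of X-ray blobs at the same resolution.

Each blob becomes a point cloud (one point per nonzero voxel, carrying its
density) capped at max_p = 2000 points; the preferred reduction cuts the
grid into N³ meta-voxels and keeps the maximum-density point of each.
Classification targets are *ligand groups* — equivalence classes of
chemistries indistinguishable by density (same heavy-atom count, ring
count, connectivity, chirality and element composition), with groups below
100 observed blobs collapsed into one "rare" class. Two architectures are
provided: a rotation-invariant point-convolution network (five invariant
convolution layers, two fully connected layers, softmax) and a
sparse-voxel feature-pyramid network with channel attention and a NetVLAD
head. Models are evaluated with classification accuracy, top-10 accuracy,
mean correct prediction rank, Brier score and macro-averaged recall, under
deposit-grouped stratified splits so no structure appears on both sides.

## Worked example

Generate a zero-inflated synthetic cryoEM-like map with two embedded
pseudo-ligands, normalize it, and extract blobs:

```r
library(ligandblob)

atoms <- data.frame(weight = c(40, 40, 30),
                    x = c(2.8, 4.0, 3.4), y = c(3.2, 3.2, 4.2), z = 6.4)
syn <- makeZeroInflatedMap(box = c(64, 64, 64), maskFraction = 0.6,
                           blobs = list(list(atoms = atoms, resolution = 2)),
                           seed = 5)
nc <- normalizeCryoemMap(syn$map, resolution = 2.0, makeCalibrationTable())
nc$threshold
#> ThresholdResult: 6.53 (quantile method, 71.1% trimmed)

blobs <- connectedComponents(nc$grid, connectivity = 26, minVoxels = 3)
blobs[[1]]
#> Blob 'NA' (NA/NA): 194 voxels, volume 1.552 A^3, centroid (3.2, 3.5, 6.4)

cloud <- sampleUniformMax(blobGrid(blobs[[1]]), maxP = 2000)
cloud
#> PointCloud: 194 points, density range [1.02, 1.55]
```

The threshold (6.53 map units) is the Φ(2.8)-quantile of the voxel values
left after trimming the ±0.5 SD window about the median (71% of voxels,
mostly the zero spike). The extracted 194-voxel component is the
high-density core of the embedded ligand, and after calibration the
lowest nonzero density equals the table target for 2.0 Å (~1.02).

Training and prediction on the synthetic 5-class shape dataset:

```r
ds <- makeShapeDataset(nClasses = 5, seed = 71)
model <- buildModel(modelConfig("riconvpp", nClasses = 5),
                    labels = sort(unique(ds$labels)), seed = 72)
trainModel(model, ds$clouds, ds$labels,
           trainConfig(learningRate = 0.01, epochs = 8, seed = 73))
tail(model@state$history, 1)
#>   epoch         loss valAccuracy
#> 8     8 0.0001708717           1

rankedLabels(predictLigand(model, ds$clouds[[1]]))[1:3]
#> [1] "line" "ring" "tshape"
```

A thin command-line interface wrapping these functions is installed at
`inst/scripts/ligandblob` (subcommands: convert, threshold, extract,
sample, group, train, predict, evaluate, synth).

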