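Package: ligandblob
Title: Ligand Identification in X-ray and CryoEM Density Maps from Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying small-molecule ligands in
    crystallographic difference maps and cryoEM difference maps. Provides
    MRC/CCP4 and compressed-array I/O for density grids, fixed-sigma and
    quantile-based density thresholding with zero-inflation trimming and
    voxel-value calibration for cryoEM maps, connected-component blob
    extraction with the standard ligand quality filters, chemical grouping of
    ligands into density-indistinguishable classes, four point-cloud sampling
    strategies, two trainable point-cloud classifiers (a rotation-invariant
    convolution stack and a sparse-voxel feature-pyramid network with channel
    attention and NetVLAD aggregation), deposit-grouped evaluation protocols,
    and synthetic density generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    ChemmineR,
    ChemmineOB
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'mrc.R'
    'npz.R'
    'resample.R'
    'normalize.R'
    'blobs.R'
    'grouping.R'
    'sampling.R'
    'autodiff.R'
    'geometry.R'
    'model-riconv.R'
    'model-minkloc.R'
    'train.R'
    'evaluate.R'
    'synthetic.R'
    'calibration-io.R'
    'zzz.R'
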