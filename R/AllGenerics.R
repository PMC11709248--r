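# Accessor generics. Slot access from user code should go through these.

#' Grid values
#' @param x a DensityMap or VoxelGrid.
#' @return The 3D numeric array of voxel values.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' Grid spacing in Angstrom
#' @param x a DensityMap or VoxelGrid.
#' @return numeric(3) for maps, scalar for voxel grids.
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' Grid origin in Angstrom
#' @param x a DensityMap, VoxelGrid or Blob.
#' @return numeric(3).
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname gridValues
#' @export
setMethod("gridValues", "DensityMap", function(x) x@values)
#' @rdname gridValues
#' @export
setMethod("gridValues", "VoxelGrid", function(x) x@values)
#' @rdname gridValues
#' @export
setMethod("gridValues", "Blob", function(x) x@grid@values)

#' @rdname gridSpacing
#' @export
setMethod("gridSpacing", "DensityMap", function(x) x@spacing)
#' @rdname gridSpacing
#' @export
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)
#' @rdname gridSpacing
#' @export
setMethod("gridSpacing", "Blob", function(x) x@grid@spacing)

#' @rdname gridOrigin
#' @export
setMethod("gridOrigin", "DensityMap", function(x) x@origin)
#' @rdname gridOrigin
#' @export
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)
#' @rdname gridOrigin
#' @export
setMethod("gridOrigin", "Blob", function(x) x@grid@origin)

#' Points of a PointCloud
#' @param x a PointCloud.
#' @return numeric matrix with columns x, y, z, density.
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))
#' @rdname cloudPoints
#' @export
setMethod("cloudPoints", "PointCloud", function(x) x@points)

#' Threshold value of a ThresholdResult
#' @param x a ThresholdResult.
#' @return The cutoff in map units.
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))
#' @rdname thresholdValue
#' @export
setMethod("thresholdValue", "ThresholdResult", function(x) x@threshold)

#' Threshold provenance statistics
#' @param x a ThresholdResult.
#' @return Named numeric with median, sd and quantile probability q.
#' @export
setGeneric("thresholdStats", function(x) standardGeneric("thresholdStats"))
#' @rdname thresholdStats
#' @export
setMethod("thresholdStats", "ThresholdResult", function(x) x@stats)

#' Blob grid
#' @param x a Blob.
#' @return The blob's \linkS4class{VoxelGrid}.
#' @export
setGeneric("blobGrid", function(x) standardGeneric("blobGrid"))
#' @rdname blobGrid
#' @export
setMethod("blobGrid", "Blob", function(x) x@grid)

#' Blob centroid
#' @param x a Blob.
#' @return numeric(3) centroid in Angstrom.
#' @export
setGeneric("blobCentroid", function(x) standardGeneric("blobCentroid"))
#' @rdname blobCentroid
#' @export
setMethod("blobCentroid", "Blob", function(x) x@centroid)

#' Split assignment
#' @param x a SplitPlan.
#' @return Named character vector, example id -> partition/fold.
#' @export
setGeneric("splitAssignment", function(x) standardGeneric("splitAssignment"))
#' @rdname splitAssignment
#' @export
setMethod("splitAssignment", "SplitPlan", function(x) x@assignment)

#' Class scores of a prediction
#' @param x a PredictionResult.
#' @return Named probability vector over ligand groups.
#' @export
setGeneric("classScores", function(x) standardGeneric("classScores"))
#' @rdname classScores
#' @export
setMethod("classScores", "PredictionResult", function(x) x@classScores)

#' Ranked labels of a prediction
#' @param x a PredictionResult.
#' @return Group labels by descending score.
#' @export
setGeneric("rankedLabels", function(x) standardGeneric("rankedLabels"))
#' @rdname rankedLabels
#' @export
setMethod("rankedLabels", "PredictionResult", function(x) x@rankedLabels)

#' Metrics as a named numeric vector
#' @param x a MetricsReport.
#' @return Named numeric with the five metrics.
#' @export
setGeneric("metricsVector", function(x) standardGeneric("metricsVector"))
#' @rdname metricsVector
#' @export
setMethod("metricsVector", "MetricsReport", function(x)
  c(accuracy = x@accuracy, top10_accuracy = x@top10Accuracy,
    mean_correct_rank = x@meanCorrectRank, brier_score = x@brierScore,
    macro_recall = x@macroRecall))
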