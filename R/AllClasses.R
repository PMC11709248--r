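#' @import methods
NULL

#' DensityMap: a 3D scalar field with physical geometry
#'
#' Container for an experimental density map: a crystallographic Fo-Fc
#' difference map (electron density, e/A^3) or a cryoEM difference map
#' (Coulomb potential, V). Values are samples on a regular grid embedded in a
#' (possibly non-orthogonal) unit cell. Axis order is always (x, y, z)
#' ascending; \code{\link{readDensityMap}} normalizes permuted files on read.
#'
#' @slot values 3D numeric array, x fastest.
#' @slot spacing numeric(3), grid step along each cell axis in Angstrom.
#' @slot origin numeric(3), Cartesian position (Angstrom) of grid node (0,0,0).
#' @slot cell 3x3 orthogonalization matrix; columns are the cell axis vectors.
#' @slot sourceKind either \code{"xray_diff"} or \code{"cryoem_diff"}.
#'
#' @exportClass DensityMap
setClass("DensityMap",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 cell = "matrix", sourceKind = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L || any(dim(object@values) < 1L))
      msg <- c(msg, "values must be a 3D array with shape >= (1,1,1)")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite values")
    if (!all(dim(object@cell) == c(3L, 3L)))
      msg <- c(msg, "cell must be a 3x3 matrix")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    if (!object@sourceKind %in% c("xray_diff", "cryoem_diff"))
      msg <- c(msg, "sourceKind must be 'xray_diff' or 'cryoem_diff'")
    if (length(msg)) msg else TRUE
  })

#' VoxelGrid: a non-negative density grid with isotropic spacing
#'
#' The canonical blob representation: voxel i (zero-based) spans the half-open
#' cube [origin + i*s, origin + (i+1)*s) and carries the density sampled at
#' its center. Canonical ligand blobs use s = 0.2 Angstrom.
#'
#' @slot values 3D non-negative numeric array, x fastest.
#' @slot spacing scalar voxel edge length in Angstrom.
#' @slot origin numeric(3), Cartesian corner (Angstrom) of voxel (0,0,0).
#'
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
        object@spacing <= 0)
      msg <- c(msg, "spacing must be a single positive value")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite values")
    if (any(!is.finite(object@values)) || any(object@values < 0))
      msg <- c(msg, "values must be finite and >= 0")
    if (length(msg)) msg else TRUE
  })

#' Blob: one connected positive-density fragment with provenance
#'
#' @slot grid a \linkS4class{VoxelGrid} cropped to the component's bounding
#'   box; all nonzero voxels form a single connected component.
#' @slot depositId PDB code (may be \code{NA}).
#' @slot chain chain identifier.
#' @slot residueNumber residue sequence number.
#' @slot ligandCode Chemical Component Dictionary code.
#' @slot centroid numeric(3), unweighted mean of nonzero voxel centers (A).
#'
#' @exportClass Blob
setClass("Blob",
  representation(grid = "VoxelGrid", depositId = "character",
                 chain = "character", residueNumber = "integer",
                 ligandCode = "character", centroid = "numeric"),
  validity = function(object) {
    if (sum(object@grid@values > 0) < 1L)
      return("blob grid must contain at least one nonzero voxel")
    TRUE
  })

#' PointCloud: order-free (x, y, z, density) points in Angstrom
#'
#' @slot points numeric matrix with columns x, y, z, density; one row per
#'   point. Densities are strictly positive.
#' @slot sourceShape integer(3), dimensions of the originating voxel grid.
#'
#' @exportClass PointCloud
setClass("PointCloud",
  representation(points = "matrix", sourceShape = "integer"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@points) != 4L)
      msg <- c(msg, "points must have 4 columns (x, y, z, density)")
    if (nrow(object@points) > 0 && any(object@points[, 4] <= 0))
      msg <- c(msg, "densities must be > 0")
    if (length(msg)) msg else TRUE
  })

#' ThresholdResult: a density cutoff and how it was obtained
#'
#' @slot threshold cutoff in map units.
#' @slot method \code{"sigma"} (fixed multiple of the map SD, X-ray) or
#'   \code{"quantile"} (empirical quantile after zero-inflation trimming,
#'   cryoEM).
#' @slot trimmedFraction fraction of voxels discarded before quantile
#'   estimation (0 for the sigma method).
#' @slot stats named numeric: \code{median}, \code{sd} of the full voxel
#'   sample and the quantile probability \code{q} (NA for sigma).
#'
#' @exportClass ThresholdResult
setClass("ThresholdResult",
  representation(threshold = "numeric", method = "character",
                 trimmedFraction = "numeric", stats = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@threshold))
      msg <- c(msg, "threshold must be finite")
    if (!object@method %in% c("sigma", "quantile"))
      msg <- c(msg, "method must be 'sigma' or 'quantile'")
    if (object@trimmedFraction < 0 || object@trimmedFraction > 1)
      msg <- c(msg, "trimmedFraction must lie in [0, 1]")
    q <- object@stats[["q"]]
    if (is.finite(q) && (q <= 0 || q >= 1))
      msg <- c(msg, "q must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' CalibrationTable: per-resolution voxel-value targets
#'
#' Maps a nominal map resolution to the target minimum nonzero voxel value
#' used to rescale cryoEM blobs onto the X-ray calibration (the mean lowest
#' nonzero value of X-ray blobs at that resolution).
#'
#' @slot resolutionBins strictly increasing bin centers (Angstrom).
#' @slot targetMinValue positive target values, one per bin.
#'
#' @exportClass CalibrationTable
setClass("CalibrationTable",
  representation(resolutionBins = "numeric", targetMinValue = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@resolutionBins) < 1L)
      msg <- c(msg, "at least one resolution bin is required")
    if (is.unsorted(object@resolutionBins, strictly = TRUE))
      msg <- c(msg, "resolution bins must be strictly increasing")
    if (length(object@targetMinValue) != length(object@resolutionBins))
      msg <- c(msg, "one target per bin required")
    if (any(object@targetMinValue <= 0))
      msg <- c(msg, "targets must be > 0")
    if (length(msg)) msg else TRUE
  })

#' MetaVoxelPartition: the uniform-sampling block decomposition
#'
#' @slot divisor the divisor N: each grid face is divided by N, giving N^3
#'   equally sized blocks (the grid is zero-padded to divisibility).
#' @slot blockShape integer(3), shape of one block (ceil(dim / N)).
#' @slot occupiedCount number of blocks containing at least one nonzero voxel.
#'
#' @exportClass MetaVoxelPartition
setClass("MetaVoxelPartition",
  representation(divisor = "integer", blockShape = "integer",
                 occupiedCount = "integer"),
  validity = function(object) {
    if (object@divisor < 1L) return("divisor must be >= 1")
    TRUE
  })

#' LigandChemistry: the density-relevant chemical descriptor of a ligand
#'
#' The grouping key: ligands identical in heavy-atom count, ring count, graph
#' connectivity, chirality and element composition cannot be told apart by
#' their density alone and share a classification label.
#'
#' @slot ccdCode Chemical Component Dictionary code.
#' @slot smiles the input SMILES string.
#' @slot heavyAtomCount number of non-hydrogen atoms.
#' @slot ringCount number of rings (cyclomatic number of the heavy-atom graph).
#' @slot connectivityKey canonical SMILES of the stereo-stripped molecule.
#' @slot chiralityKey concatenated stereo tokens of the canonical SMILES
#'   (empty for achiral ligands).
#' @slot atomicNumbers sorted atomic numbers of the heavy atoms.
#'
#' @exportClass LigandChemistry
setClass("LigandChemistry",
  representation(ccdCode = "character", smiles = "character",
                 heavyAtomCount = "integer", ringCount = "integer",
                 connectivityKey = "character", chiralityKey = "character",
                 atomicNumbers = "integer"),
  validity = function(object) {
    if (object@heavyAtomCount != length(object@atomicNumbers))
      return("heavyAtomCount must equal length(atomicNumbers)")
    TRUE
  })

#' LigandGroup: one class of density-indistinguishable ligands
#'
#' @slot groupId integer id, stable under input permutation (groups are sorted
#'   by chemical key; the rare group is last).
#' @slot memberCodes CCD codes of the member ligands.
#' @slot label representative CCD code (alphabetically first member), or
#'   \code{"rare"} for the catch-all class.
#' @slot instanceCount total number of blob instances across members.
#'
#' @exportClass LigandGroup
setClass("LigandGroup",
  representation(groupId = "integer", memberCodes = "character",
                 label = "character", instanceCount = "integer"))

#' SplitPlan: assignment of examples to partitions or folds
#'
#' Deposits (PDB entries) are the unit of assignment: two examples sharing a
#' deposit id always share an assignment, so no structure leaks across the
#' train/test boundary.
#'
#' @slot assignment named character; example id -> "train"/"val"/"test" or
#'   "fold1".."foldk".
#' @slot groupKey named character; example id -> deposit id.
#' @slot strata named character; example id -> ligand group label.
#'
#' @exportClass SplitPlan
setClass("SplitPlan",
  representation(assignment = "character", groupKey = "character",
                 strata = "character"),
  validity = function(object) {
    ids <- names(object@assignment)
    if (is.null(ids) || anyDuplicated(ids))
      return("assignment must be uniquely named by example id")
    if (!identical(sort(ids), sort(names(object@groupKey))))
      return("assignment and groupKey must cover the same ids")
    TRUE
  })

#' PredictionResult: per-class scores for one blob
#'
#' @slot classScores probability vector over ligand groups, named by group
#'   label; non-negative, sums to 1.
#' @slot rankedLabels all group labels by descending score (ties broken by
#'   class order).
#'
#' @exportClass PredictionResult
setClass("PredictionResult",
  representation(classScores = "numeric", rankedLabels = "character"),
  validity = function(object) {
    msg <- character()
    if (any(object@classScores < -1e-9))
      msg <- c(msg, "scores must be >= 0")
    if (abs(sum(object@classScores) - 1) > 1e-6)
      msg <- c(msg, "scores must sum to 1")
    if (!setequal(object@rankedLabels, names(object@classScores)))
      msg <- c(msg, "rankedLabels must be a permutation of the class labels")
    if (length(msg)) msg else TRUE
  })

#' MetricsReport: the five-metric evaluation summary
#'
#' @slot accuracy proportion of blobs whose top-ranked group is correct.
#' @slot top10Accuracy proportion with the correct group among the top 10.
#' @slot meanCorrectRank average rank of the correct group (1 = best).
#' @slot brierScore mean squared probability error for the correct class,
#'   mean((1 - p_true)^2).
#' @slot macroRecall unweighted mean of per-class recall over classes present
#'   in the truth labels.
#'
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(accuracy = "numeric", top10Accuracy = "numeric",
                 meanCorrectRank = "numeric", brierScore = "numeric",
                 macroRecall = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@accuracy > object@top10Accuracy + 1e-12)
      msg <- c(msg, "accuracy cannot exceed top-10 accuracy")
    if (object@meanCorrectRank < 1)
      msg <- c(msg, "mean correct rank must be >= 1")
    if (object@brierScore < 0 || object@brierScore > 2)
      msg <- c(msg, "Brier score out of range")
    if (object@macroRecall < 0 || object@macroRecall > 1)
      msg <- c(msg, "macro recall must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' LigandClassifier: a point-cloud ligand-group classifier
#'
#' Weights live in an environment so training updates in place; the object
#' also records the architecture configuration and the label space.
#'
#' @slot config the \code{\link{modelConfig}} list.
#' @slot params environment holding the weight matrices.
#' @slot state environment holding optimizer state and training history.
#' @slot labels class labels (ligand group labels), in score order.
#'
#' @exportClass LigandClassifier
setClass("LigandClassifier",
  representation(config = "list", params = "environment",
                 state = "environment", labels = "character"))

# ---- constructors ----------------------------------------------------------

#' Create a DensityMap
#'
#' @param values 3D numeric array (x fastest).
#' @param spacing grid step(s) in Angstrom; a scalar is recycled to 3 axes
#'   (default the canonical 0.2).
#' @param origin Cartesian position of grid node (0,0,0); default (0,0,0).
#' @param cell 3x3 cell matrix; default orthogonal cell from the grid extent.
#' @param sourceKind "xray_diff" or "cryoem_diff".
#' @return A \linkS4class{DensityMap}.
#' @export
DensityMap <- function(values, spacing = 0.2, origin = c(0, 0, 0),
                       cell = NULL, sourceKind = "xray_diff") {
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(cell)) {
    d <- dim(values)
    cell <- diag(d * spacing)
  }
  new("DensityMap", values = values, spacing = spacing,
      origin = as.numeric(origin), cell = cell, sourceKind = sourceKind)
}

#' Create a VoxelGrid
#'
#' @param values 3D non-negative numeric array.
#' @param spacing voxel edge length in Angstrom (canonical blobs use 0.2).
#' @param origin Cartesian corner of voxel (0,0,0); default (0,0,0).
#' @return A \linkS4class{VoxelGrid}.
#' @export
VoxelGrid <- function(values, spacing = 0.2, origin = c(0, 0, 0)) {
  new("VoxelGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a PointCloud
#'
#' @param points numeric matrix with columns x, y, z, density.
#' @param sourceShape dimensions of the originating grid (optional).
#' @return A \linkS4class{PointCloud}.
#' @export
PointCloud <- function(points, sourceShape = c(0L, 0L, 0L)) {
  points <- as.matrix(points)
  colnames(points) <- c("x", "y", "z", "density")
  new("PointCloud", points = points, sourceShape = as.integer(sourceShape))
}

#' Create a CalibrationTable
#'
#' @param resolutionBins strictly increasing resolutions (Angstrom).
#' @param targetMinValue positive target minimum nonzero voxel values.
#' @return A \linkS4class{CalibrationTable}.
#' @export
CalibrationTable <- function(resolutionBins, targetMinValue) {
  new("CalibrationTable", resolutionBins = as.numeric(resolutionBins),
      targetMinValue = as.numeric(targetMinValue))
}

# ---- show methods ----------------------------------------------------------

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityMap [%s]: %d x %d x %d voxels, spacing %.3g/%.3g/%.3g A\n",
              object@sourceKind, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) A; value range [%.3g, %.3g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@values), max(object@values)))
})

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  nz <- sum(object@values > 0)
  cat(sprintf("VoxelGrid: %d x %d x %d voxels @ %.3g A, %d nonzero (%.1f%%)\n",
              d[1], d[2], d[3], object@spacing, nz,
              100 * nz / prod(d)))
})

setMethod("show", "Blob", function(object) {
  nz <- sum(object@grid@values > 0)
  cat(sprintf("Blob '%s' (%s/%s): %d voxels, volume %.3f A^3, centroid (%.1f, %.1f, %.1f)\n",
              object@ligandCode, object@depositId, object@chain, nz,
              nz * object@grid@spacing^3,
              object@centroid[1], object@centroid[2], object@centroid[3]))
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points", nrow(object@points)))
  if (nrow(object@points) > 0)
    cat(sprintf(", density range [%.3g, %.3g]",
                min(object@points[, 4]), max(object@points[, 4])))
  cat("\n")
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult: %.4g (%s method, %.1f%% trimmed)\n",
              object@threshold, object@method, 100 * object@trimmedFraction))
})

setMethod("show", "MetaVoxelPartition", function(object) {
  cat(sprintf("MetaVoxelPartition: N = %d, block shape (%d, %d, %d), %d occupied\n",
              object@divisor, object@blockShape[1], object@blockShape[2],
              object@blockShape[3], object@occupiedCount))
})

setMethod("show", "LigandGroup", function(object) {
  cat(sprintf("LigandGroup %d '%s': %d member(s), %d instance(s)\n",
              object@groupId, object@label, length(object@memberCodes),
              object@instanceCount))
})

setMethod("show", "SplitPlan", function(object) {
  tab <- table(object@assignment)
  cat("SplitPlan:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      sprintf("(%d deposits)\n", length(unique(object@groupKey))))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0("MetricsReport: accuracy %.3f | top-10 %.3f | ",
                     "mean rank %.3f | Brier %.3f | macro recall %.3f\n"),
              object@accuracy, object@top10Accuracy, object@meanCorrectRank,
              object@brierScore, object@macroRecall))
})

setMethod("show", "LigandClassifier", function(object) {
  np <- sum(vapply(as.list(object@params), length, integer(1)))
  cat(sprintf("LigandClassifier [%s]: %d classes, %d parameters%s\n",
              object@config$architecture, length(object@labels), np,
              if (isTRUE(object@state$trained)) " (trained)" else ""))
})
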