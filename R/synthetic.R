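# Synthetic data generators: pseudo-ligand densities, zero-inflated
# cryoEM-like maps with ground truth, labeled shape datasets for training
# smoke tests, and synthetic calibration tables.

#' Render a pseudo-ligand density on the canonical grid
#'
#' The density is a sum of isotropic normalized Gaussians, one per atom,
#' with width sigma = 0.425 * resolution (a Gaussian whose FWHM equals the
#' nominal resolution), sampled at 0.2 A voxel centers on a grid padded
#' 3 sigma beyond the atom bounding box (wide enough that the in-grid
#' integral recovers the atom weights to ~1%). Contributions below 0.1% of
#' the blob peak are truncated to exact zero so the blob has compact
#' support; optional Gaussian noise is added and negatives are clipped.
#'
#' @param atoms data.frame with columns weight, x, y, z. The weight is the
#'   atom's total integrated density (e.g. electron count).
#' @param resolution nominal resolution in Angstrom (> 0).
#' @param noiseSd additive Gaussian noise SD in map units (default 0).
#' @param seed RNG seed for the noise.
#' @param spacing voxel edge (default the canonical 0.2 A).
#' @return A \linkS4class{VoxelGrid}.
#' @export
renderPseudoLigand <- function(atoms, resolution, noiseSd = 0, seed = 1,
                               spacing = 0.2) {
  atoms <- as.data.frame(atoms)
  if (nrow(atoms) < 1L) lbValidationError("at least one atom is required")
  if (resolution <= 0) lbValidationError("resolution must be > 0")
  sigma <- 0.425 * resolution
  pad <- 3 * sigma
  lo <- c(min(atoms$x), min(atoms$y), min(atoms$z)) - pad
  hi <- c(max(atoms$x), max(atoms$y), max(atoms$z)) + pad
  nvox <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  origin <- lo
  ax <- lapply(1:3, function(d) origin[d] + (seq_len(nvox[d]) - 0.5) * spacing)

  vals <- array(0, dim = nvox)
  norm3 <- (2 * pi * sigma^2)^(-3 / 2)
  for (a in seq_len(nrow(atoms))) {
    gx <- exp(-(ax[[1]] - atoms$x[a])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]] - atoms$y[a])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]] - atoms$z[a])^2 / (2 * sigma^2))
    vals <- vals + atoms$weight[a] * norm3 *
      (gx %o% gy %o% gz)
  }
  vals[vals < 1e-3 * max(vals)] <- 0
  if (noiseSd > 0) {
    vals <- vals + withSeed(seed, array(stats::rnorm(length(vals),
                                                     sd = noiseSd),
                                        dim = nvox))
    vals[vals < 0] <- 0
  }
  VoxelGrid(vals, spacing = spacing, origin = origin)
}

#' Generate a zero-inflated cryoEM-like map with ground truth
#'
#' Emulates a solvent-masked cryoEM difference map: Gaussian background, a
#' configurable fraction of voxels set exactly to zero (the zero-inflation
#' spike), and pseudo-ligand blobs at known locations. The masked voxels
#' are drawn outside the blob support, mirroring solvent masks that do not
#' cut through the particle. Ground-truth masks record, per blob, the voxel
#' set with density at least 1% of that blob's peak.
#'
#' @param box integer(3) grid dimensions.
#' @param maskFraction fraction of voxels zeroed (0 <= f < 1).
#' @param background c(mean, sd) of the Gaussian background.
#' @param blobs list of lists, each with elements \code{atoms} (as in
#'   \code{\link{renderPseudoLigand}}, coordinates in map Angstrom) and
#'   \code{resolution}.
#' @param seed RNG seed.
#' @param spacing voxel edge (default 0.2 A).
#' @return A list with \code{map} (a \linkS4class{DensityMap}, cryoem_diff),
#'   and \code{truthMasks} (list of linear voxel index vectors, one per
#'   blob, disjoint).
#' @export
makeZeroInflatedMap <- function(box = c(48L, 48L, 48L), maskFraction = 0.6,
                                background = c(0, 1), blobs = list(),
                                seed = 1, spacing = 0.2) {
  box <- as.integer(box)
  if (maskFraction < 0 || maskFraction >= 1)
    lbValidationError("maskFraction must lie in [0, 1)")
  nTot <- prod(box)
  withSeed(seed, {
    vals <- array(stats::rnorm(nTot, background[1], background[2]), dim = box)

    blobVals <- array(0, dim = box)
    truthMasks <- list()
    for (b in seq_along(blobs)) {
      spec <- blobs[[b]]
      g <- renderPseudoLigand(spec$atoms, spec$resolution, noiseSd = 0,
                              spacing = spacing)
      # align the blob grid into the map (both use voxel-center convention
      # with map origin at 0)
      off <- round(g@origin / spacing)
      d <- dim(g@values)
      srcLo <- pmax(1L, 1L - off)
      srcHi <- pmin(d, box - off)
      if (any(srcLo > srcHi))
        lbValidationError(sprintf("blob %d lies outside the box", b))
      dst <- lapply(1:3, function(k) (srcLo[k]:srcHi[k]) + off[k])
      src <- lapply(1:3, function(k) srcLo[k]:srcHi[k])
      sub <- g@values[src[[1]], src[[2]], src[[3]], drop = FALSE]
      region <- blobVals[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
      if (any(region > 0 & sub > 0))
        lbValidationError("blobs overlap")
      blobVals[dst[[1]], dst[[2]], dst[[3]]] <- region + sub

      mask <- array(FALSE, dim = box)
      mask[dst[[1]], dst[[2]], dst[[3]]] <- sub >= 0.01 * max(sub)
      truthMasks[[b]] <- which(mask)
    }
    support <- which(blobVals > 0)
    nMask <- round(maskFraction * nTot)
    candidates <- setdiff(seq_len(nTot), support)
    if (nMask > length(candidates))
      lbValidationError("maskFraction leaves no room for the blobs")
    masked <- sample(candidates, nMask)
    vals[masked] <- 0
    vals <- vals + blobVals
  })
  list(map = DensityMap(vals, spacing = spacing, origin = c(0, 0, 0),
                        sourceKind = "cryoem_diff"),
       truthMasks = truthMasks)
}

# shape templates for the synthetic classification dataset: distinct rigid
# arrangements, all a few Angstrom across, mimicking ligand-scale geometry
shapeTemplate <- function(name, nPoints) {
  tpos <- switch(name,
    line = cbind(seq(-4, 4, length.out = nPoints), 0, 0),
    ring = {
      a <- seq(0, 2 * pi, length.out = nPoints + 1)[-1]
      cbind(3 * cos(a), 3 * sin(a), 0)
    },
    tetrahedron = {
      v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 2.5
      v[rep(1:4, length.out = nPoints), ] +
        matrix(stats::rnorm(nPoints * 3, sd = 0.6), nPoints)
    },
    tshape = {
      n1 <- ceiling(nPoints / 2)
      rbind(cbind(seq(-4, 4, length.out = n1), 0, 0),
            cbind(0, seq(0, -5, length.out = nPoints - n1), 0))
    },
    helix = {
      t <- seq(0, 3 * pi, length.out = nPoints)
      cbind(2 * cos(t), 2 * sin(t), t / (3 * pi) * 6 - 3)
    })
  tpos
}

SHAPE_CLASSES <- c("line", "ring", "tetrahedron", "tshape", "helix")

#' Generate a labeled multi-class shape dataset
#'
#' A stand-in for the ligand-group data at desk scale: each class is a
#' distinct rigid arrangement of points (line, ring, tetrahedron, T-shape,
#' helix) a few Angstrom across, drawn with a random 3D rotation, positional
#' jitter and near-constant density. Classes are balanced and separable by
#' rotation-invariant shape statistics by construction.
#'
#' @param nClasses number of classes (2..5).
#' @param nPerClass clouds per class (default 200).
#' @param nPoints points per cloud (default 48).
#' @param maxP maximum cloud size; clouds are capped at this budget.
#' @param jitterSd positional jitter SD in Angstrom.
#' @param seed RNG seed; the dataset is bit-reproducible given the seed.
#' @return A list with \code{clouds} (list of \linkS4class{PointCloud}) and
#'   \code{labels} (character vector of class names).
#' @export
makeShapeDataset <- function(nClasses = 5, nPerClass = 200, nPoints = 48,
                             maxP = 2000, jitterSd = 0.15, seed = 1) {
  if (nClasses < 2 || nClasses > length(SHAPE_CLASSES))
    lbValidationError(sprintf("nClasses must be in 2..%d", length(SHAPE_CLASSES)))
  nPoints <- min(nPoints, maxP)
  classes <- SHAPE_CLASSES[seq_len(nClasses)]
  clouds <- vector("list", nClasses * nPerClass)
  labels <- character(nClasses * nPerClass)
  i <- 0L
  withSeed(seed, {
    for (cl in classes) {
      for (r in seq_len(nPerClass)) {
        pos <- shapeTemplate(cl, nPoints)
        pos <- pos + matrix(stats::rnorm(length(pos), sd = jitterSd),
                            nrow(pos))
        pos <- pos %*% t(randomRotation())
        dens <- 1 + abs(stats::rnorm(nrow(pos), sd = 0.1))
        i <- i + 1L
        clouds[[i]] <- PointCloud(cbind(pos, dens),
                                  sourceShape = c(0L, 0L, 0L))
        labels[i] <- cl
      }
    }
  })
  list(clouds = clouds, labels = labels)
}

# uniform random rotation matrix via QR of a Gaussian matrix
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic calibration table
#'
#' Targets decrease with the resolution value (higher resolution, i.e.
#' smaller Angstrom, gives denser minimum values), mimicking the shape of
#' X-ray-derived calibration without claiming its values.
#'
#' @param resolutions bin centers in Angstrom (default 1.0 to 4.0 by 0.1,
#'   matching 0.1 A binning).
#' @param seed RNG seed for the mild jitter on the trend.
#' @return A \linkS4class{CalibrationTable}.
#' @export
makeCalibrationTable <- function(resolutions = seq(1, 4, by = 0.1), seed = 1) {
  resolutions <- sort(unique(resolutions))
  base <- 0.3 + 1.5 / resolutions
  jitter <- withSeed(seed, stats::runif(length(base), 0.95, 1.05))
  CalibrationTable(resolutions, base * jitter)
}
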