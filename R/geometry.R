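# Geometric preprocessing shared by the classifiers: k-nearest neighbors,
# local reference axes, rotation-invariant neighborhood features, and sparse
# voxelization. All of it is parameter-free, so it is computed once per
# cloud and cached across training epochs.

knnIndices <- function(xyz, k) {
  n <- nrow(xyz)
  k <- min(k, n)
  d2 <- as.matrix(stats::dist(xyz))^2
  t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
}

# Local reference axis per point: the eigenvector of the neighborhood
# covariance with the smallest eigenvalue (the local "normal"), sign-fixed
# towards the cloud centroid so the axis is deterministic. Rotating the
# cloud rotates the axes with it, which makes every feature built from dot
# products of axes and offsets rotation invariant.
localReferenceAxes <- function(xyz, nn) {
  n <- nrow(xyz)
  centroid <- colMeans(xyz)
  axes <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- xyz[nn[i, ], , drop = FALSE]
    cv <- stats::cov(nb)
    if (any(!is.finite(cv)) || nrow(nb) < 3L) {
      a <- centroid - xyz[i, ]
    } else {
      eg <- eigen(cv, symmetric = TRUE)
      a <- eg$vectors[, 3]
    }
    toC <- centroid - xyz[i, ]
    s <- sum(a * toC)
    if (abs(s) > 1e-12 && s < 0) a <- -a
    nrm <- sqrt(sum(a^2))
    axes[i, ] <- if (nrm > 1e-12) a / nrm else c(0, 0, 0)
  }
  axes
}

# Rotation-invariant features for each (point, neighbor) pair, stacked as an
# (n*k) x F matrix with neighbors of point i in rows (i-1)*k + 1 .. i*k.
# Features: neighbor distance; projections of the offset on both local axes;
# axis alignment; neighbor distance to centroid; neighbor axis vs centroid
# direction; neighbor density. All are preserved under rigid rotation.
riconvFeatures <- function(xyz, dens, nn, axes) {
  n <- nrow(xyz); k <- ncol(nn)
  centroid <- colMeans(xyz)
  iRep <- rep(seq_len(n), each = k)
  jFlat <- as.vector(t(nn))
  off <- xyz[jFlat, , drop = FALSE] - xyz[iRep, , drop = FALSE]
  r <- sqrt(rowSums(off^2))
  u <- off / ifelse(r > 1e-12, r, 1)
  ai <- axes[iRep, , drop = FALSE]
  aj <- axes[jFlat, , drop = FALSE]
  toC <- sweep(-xyz[jFlat, , drop = FALSE], 2, -centroid, "+")
  rc <- sqrt(rowSums(toC^2))
  uc <- toC / ifelse(rc > 1e-12, rc, 1)
  cbind(r,
        rowSums(ai * u),
        rowSums(aj * u),
        rowSums(ai * aj),
        rc,
        rowSums(aj * uc),
        dens[jFlat])
}

prepareRiconvInput <- function(cloud, cfg) {
  pts <- cloudPoints(cloud)
  xyz <- pts[, 1:3, drop = FALSE]
  dens <- as.vector(pts[, 4])
  dens <- dens / (mean(dens) + 1e-12)   # per-cloud density scale removal
  k <- min(cfg$neighborhoodK, nrow(xyz))
  nn <- knnIndices(xyz, k)
  axes <- localReferenceAxes(xyz, nn)
  feats <- riconvFeatures(xyz, dens, nn, axes)
  list(n = nrow(xyz), k = k, nnFlat = as.vector(t(nn)), geo = feats)
}

# Sparse voxelization for the voxel-convolution network. Coordinates are
# quantized at cfg$quantizationSize; duplicate voxels keep their maximum
# density. Voxels are sorted (z, y, x) so the representation is independent
# of input point order. For each pyramid level the 27 kernel-offset
# neighbor tables and the stride-2 parent map are precomputed.
prepareMinklocInput <- function(cloud, cfg) {
  pts <- cloudPoints(cloud)
  q <- cfg$quantizationSize
  vox <- floor(pts[, 1:3, drop = FALSE] / q)
  key <- paste(vox[, 1], vox[, 2], vox[, 3])
  ord <- order(vox[, 3], vox[, 2], vox[, 1])
  vox <- vox[ord, , drop = FALSE]
  key <- key[ord]
  dens <- pts[ord, 4]
  first <- !duplicated(key)
  coords <- vox[first, , drop = FALSE]
  feat <- as.numeric(tapply(dens, factor(key, levels = key[first]), max))
  feat <- feat / (mean(feat) + 1e-12)

  levels <- list()
  cur <- coords
  for (l in seq_len(3L)) {
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    keyCur <- paste(cur[, 1], cur[, 2], cur[, 3])
    nbr <- matrix(0L, nrow(cur), 27L)
    for (o in seq_len(27L)) {
      shifted <- sweep(cur, 2, offs[o, ], "+")
      nbr[, o] <- match(paste(shifted[, 1], shifted[, 2], shifted[, 3]),
                        keyCur, nomatch = 0L)
    }
    coarse <- floor(cur / 2)
    keyCoarse <- paste(coarse[, 1], coarse[, 2], coarse[, 3])
    ordC <- order(coarse[, 3], coarse[, 2], coarse[, 1])
    uniq <- !duplicated(keyCoarse[ordC])
    coarseCoords <- coarse[ordC, , drop = FALSE][uniq, , drop = FALSE]
    parent <- match(keyCoarse,
                    paste(coarseCoords[, 1], coarseCoords[, 2],
                          coarseCoords[, 3]))
    levels[[l]] <- list(nVox = nrow(cur), nbr = nbr, parent = parent,
                        nCoarse = nrow(coarseCoords))
    cur <- coarseCoords
  }
  list(feat = matrix(feat, ncol = 1), levels = levels)
}
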