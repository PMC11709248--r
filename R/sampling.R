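# Point-cloud conversion and the four sampling strategies that cap a blob at
# max_p points: random, uniform (meta-voxel maximum), surface, clustering.

#' Convert a voxel grid to a point cloud
#'
#' One point per nonzero voxel, positioned at the voxel center and carrying
#' the voxel's density.
#'
#' @param grid a \linkS4class{VoxelGrid} with at least one nonzero voxel.
#' @return A \linkS4class{PointCloud}.
#' @export
gridToPointCloud <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  lin <- which(grid@values > 0)
  if (length(lin) == 0L)
    lbDegenerateError("all-zero grid has no points")
  idx0 <- arrayIndices3d(lin, dim(grid@values))
  centers <- voxelCenters(idx0, grid@spacing, grid@origin)
  PointCloud(cbind(centers, grid@values[lin]),
             sourceShape = dim(grid@values))
}

#' Partition a grid into meta-voxels for uniform sampling
#'
#' Finds the divisor N that cuts the grid into N^3 equally sized blocks
#' (shape ceil(dim / N) per axis, zero-padded) such that the number of
#' blocks containing nonzero voxels stays within \code{maxP}. N starts at 1
#' and is incremented by 1 while the next N keeps the occupied count within
#' the bound, so the occupied count ends as close to \code{maxP} as the
#' (possibly non-monotonic) sequence allows; N never exceeds the largest
#' grid dimension (blocks are never smaller than one voxel).
#'
#' @param shape integer(3) grid dimensions.
#' @param nonzeroMask logical or numeric 3D array marking nonzero voxels.
#' @param maxP point budget (>= 1).
#' @return A \linkS4class{MetaVoxelPartition}.
#' @export
partitionMetaVoxels <- function(shape, nonzeroMask, maxP = 2000) {
  shape <- as.integer(shape)
  if (maxP < 1) lbValidationError("maxP must be >= 1")
  idx0 <- arrayIndices3d(which(nonzeroMask != 0), shape)
  n <- 1L
  nMax <- max(shape)
  while (n < nMax && metaVoxelOccupancy(shape, idx0, n + 1L) <= maxP)
    n <- n + 1L
  new("MetaVoxelPartition", divisor = n,
      blockShape = as.integer(ceiling(shape / n)),
      occupiedCount = metaVoxelOccupancy(shape, idx0, n))
}

# number of occupied N^3 blocks for divisor n
metaVoxelOccupancy <- function(shape, idx0, n) {
  if (nrow(idx0) == 0L) return(0L)
  bs <- ceiling(shape / n)
  blk <- floor(sweep(idx0, 2, bs, "/"))
  length(unique(blk[, 1] + n * (blk[, 2] + n * blk[, 3])))
}

#' Uniform sampling: the maximum-density point per meta-voxel
#'
#' The preferred sampling strategy: partition the grid into meta-voxels
#' (see \code{\link{partitionMetaVoxels}}) and keep, from each occupied
#' block, the voxel with maximum density. Sampled points retain their
#' original coordinates and density. Equal maxima within a block are broken
#' towards the lowest (z, y, x) voxel index, making the result fully
#' deterministic and independent of point order.
#'
#' @param grid a \linkS4class{VoxelGrid} with at least one nonzero voxel.
#' @param maxP point budget (default 2000).
#' @return A \linkS4class{PointCloud} with at most \code{maxP} points.
#' @export
sampleUniformMax <- function(grid, maxP = 2000) {
  stopifnot(is(grid, "VoxelGrid"))
  d <- dim(grid@values)
  lin <- which(grid@values > 0)
  if (length(lin) == 0L) lbDegenerateError("empty point cloud")
  idx0 <- arrayIndices3d(lin, d)
  if (length(lin) <= maxP)
    return(gridToPointCloud(grid))

  part <- partitionMetaVoxels(d, grid@values != 0, maxP)
  n <- part@divisor
  bs <- part@blockShape
  blk <- floor(sweep(idx0, 2, bs, "/"))
  blockId <- blk[, 1] + n * (blk[, 2] + n * blk[, 3])
  dens <- grid@values[lin]
  # tie-break on lowest (z, y, x): order candidates so the preferred voxel
  # comes first, then keep the first maximum per block
  ord <- order(blockId, -dens, idx0[, 3], idx0[, 2], idx0[, 1])
  first <- !duplicated(blockId[ord])
  sel <- ord[first]
  centers <- voxelCenters(idx0[sel, , drop = FALSE], grid@spacing,
                          grid@origin)
  PointCloud(cbind(centers, dens[sel]), sourceShape = d)
}

#' Random point sampling
#'
#' Uniform without-replacement selection of min(maxP, n) points.
#'
#' @param pc a \linkS4class{PointCloud}.
#' @param maxP point budget.
#' @param seed RNG seed; identical seeds give identical samples.
#' @return A \linkS4class{PointCloud}.
#' @export
sampleRandom <- function(pc, maxP = 2000, seed = 1) {
  stopifnot(is(pc, "PointCloud"))
  n <- nrow(pc@points)
  if (n == 0L) lbDegenerateError("empty point cloud")
  if (n <= maxP) return(pc)
  sel <- withSeed(seed, sample.int(n, maxP))
  PointCloud(pc@points[sel, , drop = FALSE], sourceShape = pc@sourceShape)
}

#' Surface (outer shell) sampling
#'
#' The shell is the set of nonzero voxels with at least one zero or
#' out-of-bounds face neighbor (6-connectivity); min(maxP, shell size)
#' points are drawn uniformly without replacement from it.
#'
#' @param grid a \linkS4class{VoxelGrid} with at least one nonzero voxel.
#' @param maxP point budget.
#' @param seed RNG seed.
#' @return A \linkS4class{PointCloud} of shell points.
#' @export
sampleSurface <- function(grid, maxP = 2000, seed = 1) {
  stopifnot(is(grid, "VoxelGrid"))
  v <- grid@values
  d <- dim(v)
  if (!any(v > 0)) lbDegenerateError("empty point cloud")
  occ <- v > 0
  # padded occupancy: out-of-bounds counts as empty
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  coreIdx <- function(dx, dy, dz)
    pad[(2 + dx):(d[1] + 1 + dx), (2 + dy):(d[2] + 1 + dy),
        (2 + dz):(d[3] + 1 + dz)]
  allNeighborsFull <- coreIdx(-1, 0, 0) & coreIdx(1, 0, 0) &
    coreIdx(0, -1, 0) & coreIdx(0, 1, 0) & coreIdx(0, 0, -1) & coreIdx(0, 0, 1)
  shell <- occ & !allNeighborsFull
  lin <- which(shell)
  sel <- if (length(lin) <= maxP) lin else
    withSeed(seed, sort(sample(lin, maxP)))
  idx0 <- arrayIndices3d(sel, d)
  centers <- voxelCenters(idx0, grid@spacing, grid@origin)
  PointCloud(cbind(centers, v[sel]), sourceShape = d)
}

#' Clustering (k-means centroid) sampling
#'
#' If the cloud exceeds \code{maxP} points, k-means with k = maxP (seeded
#' k-means++ initialization, at most 50 Lloyd iterations) is run on the
#' coordinates and the centroids become the sampled points. Each centroid
#' carries the density of its nearest original point, keeping values at the
#' original scale. Clouds within budget are returned unchanged.
#'
#' @param pc a \linkS4class{PointCloud}.
#' @param maxP point budget (the k of k-means).
#' @param seed RNG seed.
#' @return A \linkS4class{PointCloud} with exactly min(maxP, n) points.
#' @export
sampleClustering <- function(pc, maxP = 2000, seed = 1) {
  stopifnot(is(pc, "PointCloud"))
  n <- nrow(pc@points)
  if (n == 0L) lbDegenerateError("empty point cloud")
  if (n <= maxP) return(pc)
  xyz <- pc@points[, 1:3, drop = FALSE]
  centers <- withSeed(seed, {
    init <- kmeansPlusPlusInit(xyz, maxP)
    km <- suppressWarnings(stats::kmeans(xyz, centers = init, iter.max = 50,
                                         algorithm = "Lloyd"))
    km$centers
  })
  dens <- pc@points[nearestRowIndex(centers, xyz), 4]
  PointCloud(cbind(centers, dens), sourceShape = pc@sourceShape)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# points sampled with probability proportional to squared distance to the
# nearest chosen center.
kmeansPlusPlusInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L, ] <- x[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1L, ])^2))
  }
  centers
}

nearestRowIndex <- function(query, ref) {
  vapply(seq_len(nrow(query)), function(i) {
    which.min(colSums((t(ref) - query[i, ])^2))
  }, integer(1))
}
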