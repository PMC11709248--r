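# Resampling of density maps onto the canonical isotropic grid.

#' Resample a density map onto an isotropic voxel grid
#'
#' Interpolates the map trilinearly at the centers of a new isotropic grid
#' covering the map's Cartesian bounding box. Interpolation happens in
#' fractional (grid index) coordinates via the cell matrix, so non-orthogonal
#' crystallographic cells are handled. Samples falling outside the map are 0;
#' negative interpolated values are clipped to 0 so the result is a valid
#' blob grid.
#'
#' The output origin is placed half a voxel before the map's first node, so a
#' map already at the target spacing reproduces its node values exactly
#' (voxel centers then coincide with map nodes).
#'
#' @param map a \linkS4class{DensityMap}.
#' @param spacing target voxel edge in Angstrom (canonical 0.2).
#' @return A \linkS4class{VoxelGrid}.
#' @export
resampleToGrid <- function(map, spacing = 0.2) {
  stopifnot(is(map, "DensityMap"))
  if (spacing <= 0) lbValidationError("target spacing must be > 0")
  d <- dim(map@values)
  unitAxes <- sweep(map@cell, 2, sqrt(colSums(map@cell^2)), "/")
  step <- unitAxes %*% diag(map@spacing)   # columns: node-to-node step vectors
  if (abs(det(step)) < 1e-12)
    lbValidationError("cell matrix is not invertible")

  # Cartesian bounding box over the 8 extreme nodes
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  cart <- t(step %*% t(corners)) + matrix(map@origin, nrow = 8, ncol = 3,
                                          byrow = TRUE)
  lo <- apply(cart, 2, min)
  hi <- apply(cart, 2, max)
  nOut <- pmax(1L, as.integer(floor((hi - lo) / spacing + 1e-9)) + 1L)
  origin <- lo - 0.5 * spacing   # centers at lo + i * spacing

  ax <- lo[1] + (seq_len(nOut[1]) - 1) * spacing
  ay <- lo[2] + (seq_len(nOut[2]) - 1) * spacing
  az <- lo[3] + (seq_len(nOut[3]) - 1) * spacing
  pts <- cbind(rep(ax, times = nOut[2] * nOut[3]),
               rep(rep(ay, each = nOut[1]), times = nOut[3]),
               rep(az, each = nOut[1] * nOut[2]))
  idx <- t(solve(step, t(sweep(pts, 2, map@origin))))  # fractional indices

  out <- trilinearSample(map@values, idx)
  out[out < 0] <- 0
  VoxelGrid(array(out, dim = nOut), spacing = spacing, origin = origin)
}

# Trilinear interpolation of a 3D array at fractional zero-based indices.
# Out-of-range points return 0.
trilinearSample <- function(values, idx) {
  d <- dim(values)
  eps <- 1e-9
  inb <- idx[, 1] >= -eps & idx[, 1] <= d[1] - 1 + eps &
         idx[, 2] >= -eps & idx[, 2] <= d[2] - 1 + eps &
         idx[, 3] >= -eps & idx[, 3] <= d[3] - 1 + eps
  out <- numeric(nrow(idx))
  if (!any(inb)) return(out)
  p <- idx[inb, , drop = FALSE]
  p[, 1] <- pmin(pmax(p[, 1], 0), d[1] - 1)
  p[, 2] <- pmin(pmax(p[, 2], 0), d[2] - 1)
  p[, 3] <- pmin(pmax(p[, 3], 0), d[3] - 1)
  i0 <- pmin(floor(p), matrix(rep(d - 2L, each = nrow(p)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- p - i0
  gather <- function(dx, dy, dz)  # clamp: corners with weight 0 may fall outside
    values[cbind(pmin(i0[, 1] + dx, d[1] - 1) + 1,
                 pmin(i0[, 2] + dy, d[2] - 1) + 1,
                 pmin(i0[, 3] + dz, d[3] - 1) + 1)]
  acc <-
    gather(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    gather(1, 0, 0) * f[, 1]       * (1 - f[, 2]) * (1 - f[, 3]) +
    gather(0, 1, 0) * (1 - f[, 1]) * f[, 2]       * (1 - f[, 3]) +
    gather(1, 1, 0) * f[, 1]       * f[, 2]       * (1 - f[, 3]) +
    gather(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    gather(1, 0, 1) * f[, 1]       * (1 - f[, 2]) * f[, 3] +
    gather(0, 1, 1) * (1 - f[, 1]) * f[, 2]       * f[, 3] +
    gather(1, 1, 1) * f[, 1]       * f[, 2]       * f[, 3]
  out[inb] <- acc
  out
}
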