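# Independent oracles used across the suite. These deliberately re-derive
# results with the most naive algorithm available so they cannot share bugs
# with the implementation.

# iterative flood fill over nonzero voxels; returns integer labels in
# column-major order (0 = background)
floodFillOracle <- function(values, connectivity) {
  d <- dim(values)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ord <- rowSums(abs(offsets))
  offsets <- offsets[ord > 0 & ord <= switch(as.character(connectivity),
                                             "6" = 1, "18" = 2, "26" = 3), ,
                     drop = FALSE]
  labels <- array(0L, d)
  cur <- 0L
  for (start in which(values != 0)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    labels[start] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (v - 1L) %% d[1] + 1L
      j <- ((v - 1L) %/% d[1]) %% d[2] + 1L
      k <- (v - 1L) %/% (d[1] * d[2]) + 1L
      for (o in seq_len(nrow(offsets))) {
        ii <- i + offsets[o, 1]; jj <- j + offsets[o, 2]; kk <- k + offsets[o, 3]
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
          next
        w <- ii + d[1] * ((jj - 1L) + d[2] * (kk - 1L))
        if (values[w] != 0 && labels[w] == 0L) {
          labels[w] <- cur
          stack <- c(stack, w)
        }
      }
    }
  }
  as.vector(labels)
}

# type-7 quantile by explicit sorting and linear interpolation
quantileSortOracle <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# brute-force meta-voxel divisor search implementing the iterative stop rule
# (start at N = 1, increment while the next N keeps the occupied block count
# within the budget, never exceeding the largest dimension)
bruteForceDivisor <- function(shape, mask, maxP) {
  occ <- function(n) {
    bs <- ceiling(shape / n)
    idx <- which(mask != 0, arr.ind = TRUE) - 1L
    if (nrow(idx) == 0L) return(0L)
    blk <- floor(idx / matrix(bs, nrow(idx), 3, byrow = TRUE))
    nrow(unique(blk))
  }
  n <- 1L
  while (n < max(shape) && occ(n + 1L) <= maxP) n <- n + 1L
  list(n = n, occupied = occ(n))
}

# rotation-invariant shape moments for the nearest-centroid separability
# oracle: covariance eigenvalues plus radial distance statistics
shapeMoments <- function(cloud) {
  xyz <- cloudPoints(cloud)[, 1:3, drop = FALSE]
  c0 <- colMeans(xyz)
  r <- sqrt(rowSums((xyz - matrix(c0, nrow(xyz), 3, byrow = TRUE))^2))
  ev <- sort(eigen(stats::cov(xyz), symmetric = TRUE,
                   only.values = TRUE)$values)
  c(ev, mean(r), stats::sd(r), max(r))
}

nearestCentroidAccuracy <- function(features, labels) {
  mu <- colMeans(features); sdv <- apply(features, 2, stats::sd)
  z <- scale(features, mu, pmax(sdv, 1e-9))
  classes <- sort(unique(labels))
  centroids <- t(vapply(classes, function(cl)
    colMeans(z[labels == cl, , drop = FALSE]), numeric(ncol(z))))
  pred <- classes[apply(z, 1, function(row)
    which.min(colSums((t(centroids) - row)^2)))]
  mean(pred == labels)
}

randomRotationMatrix <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotateCloud <- function(cloud, R) {
  pts <- cloudPoints(cloud)
  PointCloud(cbind(pts[, 1:3, drop = FALSE] %*% t(R), pts[, 4]))
}

randomCloud <- function(n, scale = 5) {
  PointCloud(cbind(matrix(stats::runif(n * 3, -scale, scale), n),
                   stats::runif(n, 0.5, 2)))
}

# map a blob (cropped grid) back to linear voxel indices of the parent grid
blobMapIndices <- function(blob, parentGrid) {
  g <- blobGrid(blob)
  d <- dim(gridValues(g))
  lin <- which(gridValues(g) > 0) - 1L
  idx <- cbind(lin %% d[1],
               (lin %/% d[1]) %% d[2],
               lin %/% (d[1] * d[2]))
  off <- round((gridOrigin(g) - gridOrigin(parentGrid)) /
                 gridSpacing(parentGrid))
  idx <- idx + matrix(off, nrow(idx), 3, byrow = TRUE)
  dp <- dim(gridValues(parentGrid))
  idx[, 1] + 1L + dp[1] * (idx[, 2] + dp[2] * idx[, 3])
}
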