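# Point-cloud conversion and the four sampling strategies.

test_that("grid to point cloud places points at voxel centers", {
  a <- array(0, c(3, 3, 3)); a[1, 1, 1] <- 2.5
  pc <- gridToPointCloud(VoxelGrid(a, spacing = 0.2, origin = c(0, 0, 0)))
  expect_identical(nrow(cloudPoints(pc)), 1L)
  expect_equal(unname(cloudPoints(pc)[1, ]), c(0.1, 0.1, 0.1, 2.5))

  set.seed(41)
  v <- array(rbinom(6^3, 1, 0.4) * runif(6^3, 0.5, 2), c(6, 6, 6))
  pc2 <- gridToPointCloud(VoxelGrid(v))
  expect_identical(nrow(cloudPoints(pc2)), sum(v > 0))
  expect_setequal(cloudPoints(pc2)[, 4], v[v > 0])

  expect_error(gridToPointCloud(VoxelGrid(array(0, c(2, 2, 2)))),
               class = "ligandblob_degenerate_error")
})

test_that("meta-voxel partition matches the worked example and the oracle", {
  full <- array(1, c(20, 16, 10))
  # divisor 2 yields 8 blocks of shape (10, 8, 5)
  expect_identical(ligandblob:::metaVoxelOccupancy(
    c(20L, 16L, 10L),
    ligandblob:::arrayIndices3d(seq_len(prod(c(20, 16, 10))), c(20, 16, 10)),
    2L), 8L)
  expect_identical(as.integer(ceiling(c(20, 16, 10) / 2)), c(10L, 8L, 5L))

  part <- partitionMetaVoxels(c(20, 16, 10), full, maxP = 8)
  expect_identical(part@occupiedCount, 8L)
  expect_identical(part@blockShape, c(10L, 8L, 5L))

  # fully occupied cube: brute-force N scan agrees
  cube <- array(1, c(8, 8, 8))
  p8 <- partitionMetaVoxels(c(8, 8, 8), cube, maxP = 2000)
  oracle <- bruteForceDivisor(c(8, 8, 8), cube, 2000)
  expect_identical(p8@divisor, as.integer(oracle$n))
  expect_lte(p8@occupiedCount, 2000L)

  # random sparse masks across budgets
  set.seed(42)
  for (rep in 1:8) {
    d <- sample(3:14, 3, replace = TRUE)
    mask <- array(rbinom(prod(d), 1, runif(1, 0.1, 0.9)), d)
    for (maxP in c(1, 7, 25, 200)) {
      got <- partitionMetaVoxels(d, mask, maxP)
      want <- bruteForceDivisor(d, mask, maxP)
      expect_identical(got@divisor, as.integer(want$n))
      expect_identical(got@occupiedCount, as.integer(want$occupied))
      expect_lte(got@occupiedCount, maxP)
    }
  }

  # masks within budget refine all the way to single-voxel blocks
  tiny <- array(0, c(9, 9, 9)); tiny[1:5] <- 1
  p <- partitionMetaVoxels(c(9, 9, 9), tiny, maxP = 2000)
  expect_identical(p@blockShape, c(1L, 1L, 1L))
})

test_that("uniform-max keeps per-block maxima at original coordinates", {
  ramp <- array(as.numeric(1:64), c(4, 4, 4))
  g <- VoxelGrid(ramp)
  out <- sampleUniformMax(g, maxP = 8)
  octantMax <- sort(sapply(split(1:64, list(
    rep(rep(1:2, each = 2), 16),
    rep(rep(1:2, each = 8), times = 4),
    rep(1:2, each = 32))), function(ix) max(ramp[ix])))
  expect_setequal(cloudPoints(out)[, 4], octantMax)

  # under budget: identity
  pc <- gridToPointCloud(g)
  expect_identical(cloudPoints(sampleUniformMax(g, maxP = 2000)),
                   cloudPoints(pc))

  # output points are a sub-multiset of the input cloud
  set.seed(43)
  v <- array(rbinom(10^3, 1, 0.6) * runif(10^3, 0.1, 3), c(10, 10, 10))
  gv <- VoxelGrid(v)
  sampled <- cloudPoints(sampleUniformMax(gv, maxP = 40))
  allPts <- cloudPoints(gridToPointCloud(gv))
  keys <- apply(allPts, 1, paste, collapse = "/")
  expect_true(all(apply(sampled, 1, paste, collapse = "/") %in% keys))
  expect_lte(nrow(sampled), 40L)
})

test_that("random sampling is seeded, uniform and within budget", {
  set.seed(44)
  pc <- randomCloud(10)
  expect_identical(cloudPoints(sampleRandom(pc, 20, seed = 9)),
                   cloudPoints(pc))   # under budget
  s1 <- sampleRandom(pc, 5, seed = 7)
  s2 <- sampleRandom(pc, 5, seed = 7)
  expect_identical(cloudPoints(s1), cloudPoints(s2))

  # inclusion frequency of each point over many seeded draws is ~ 1/2
  counts <- numeric(10)
  keys <- apply(cloudPoints(pc), 1, paste, collapse = "/")
  for (s in 1:10000) {
    got <- apply(cloudPoints(sampleRandom(pc, 5, seed = s)), 1,
                 paste, collapse = "/")
    counts[keys %in% got] <- counts[keys %in% got] + 1
  }
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_true(all(abs(counts / 10000 - 0.5) < 3 * se + 1e-9))
})

test_that("surface sampling draws from the 6-connectivity shell", {
  solid <- VoxelGrid(array(1, c(5, 5, 5)))
  shell <- sampleSurface(solid, maxP = 1000, seed = 1)
  expect_equal(nrow(cloudPoints(shell)), 5^3 - 3^3)  # 98

  single <- array(0, c(3, 3, 3)); single[2, 2, 2] <- 1
  expect_identical(nrow(cloudPoints(sampleSurface(VoxelGrid(single), 10, 1))),
                   1L)

  # every sampled point has a zero (or out-of-bounds) face neighbor
  set.seed(45)
  v <- array(rbinom(8^3, 1, 0.7), c(8, 8, 8))
  out <- cloudPoints(sampleSurface(VoxelGrid(v), maxP = 30, seed = 2))
  idx <- round(out[, 1:3] / 0.2 + 0.5)   # back to 1-based voxel indices
  hasZeroNeighbor <- function(i, j, k) {
    for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1))) {
      ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
      if (ii < 1 || ii > 8 || jj < 1 || jj > 8 || kk < 1 || kk > 8)
        return(TRUE)
      if (v[ii, jj, kk] == 0) return(TRUE)
    }
    FALSE
  }
  expect_true(all(mapply(hasZeroNeighbor, idx[, 1], idx[, 2], idx[, 3])))
})

test_that("clustering sampling returns centroids with original-scale density", {
  set.seed(46)
  c1 <- matrix(rnorm(300, 0, 0.3), 100)
  c2 <- matrix(rnorm(300, 0, 0.3), 100) + 10
  pc <- PointCloud(cbind(rbind(c1, c2), runif(200, 0.5, 2)))
  out <- sampleClustering(pc, maxP = 2, seed = 5)
  centers <- cloudPoints(out)[, 1:3]
  means <- rbind(colMeans(c1), colMeans(c2))
  ord <- order(centers[, 1])
  expect_lt(max(abs(centers[ord, ] - means[order(means[, 1]), ])), 0.1)
  # densities come from real points
  expect_true(all(cloudPoints(out)[, 4] %in% cloudPoints(pc)[, 4]))

  expect_identical(cloudPoints(sampleClustering(pc, maxP = 200, seed = 1)),
                   cloudPoints(pc))   # |pc| <= maxP: identity
  expect_identical(nrow(cloudPoints(sampleClustering(pc, 50, seed = 2))), 50L)
  # determinism
  expect_identical(cloudPoints(sampleClustering(pc, 17, seed = 3)),
                   cloudPoints(sampleClustering(pc, 17, seed = 3)))
})

test_that("all strategies respect the point budget and provenance", {
  set.seed(47)
  v <- array(rbinom(12^3, 1, 0.5) * runif(12^3, 0.2, 4), c(12, 12, 12))
  g <- VoxelGrid(v)
  pc <- gridToPointCloud(g)
  maxP <- 100
  outs <- list(uniform = sampleUniformMax(g, maxP),
               random = sampleRandom(pc, maxP, seed = 1),
               surface = sampleSurface(g, maxP, seed = 1),
               clustering = sampleClustering(pc, maxP, seed = 1))
  keys <- apply(cloudPoints(pc), 1, paste, collapse = "/")
  for (nm in names(outs)) {
    expect_lte(nrow(cloudPoints(outs[[nm]])), maxP)
    if (nm != "clustering") {
      got <- apply(cloudPoints(outs[[nm]]), 1, paste, collapse = "/")
      expect_true(all(got %in% keys), info = nm)
    }
  }

  # uniform-max is invariant to input point order (it reads the grid)
  expect_identical(cloudPoints(sampleUniformMax(g, maxP)),
                   cloudPoints(sampleUniformMax(g, maxP)))
})
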