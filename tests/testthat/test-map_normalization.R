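# Density cutoffs: fixed-sigma (X-ray) and the three-step cryoEM
# normalization (zero-inflation trimming, quantile thresholding, rescaling).

test_that("sigma threshold is k times the population SD", {
  m <- DensityMap(array(c(-1, 1, -1, 1, -1, 1, -1, 1), c(2, 2, 2)))
  thr <- sigmaThreshold(m)
  expect_equal(thresholdValue(thr), 2.8)
  expect_identical(thr@method, "sigma")

  set.seed(11)
  draws <- rnorm(1e5)
  m2 <- DensityMap(array(draws, c(100, 100, 10)))
  bruteSd <- sqrt(mean((draws - mean(draws))^2))
  expect_equal(thresholdValue(sigmaThreshold(m2)), 2.8 * bruteSd,
               tolerance = 1e-12)
  # SD of 1e5 standard-normal draws is within 3 standard errors of 1
  expect_lt(abs(thresholdValue(sigmaThreshold(m2)) - 2.8),
            3 * 2.8 * sqrt(1 / (2 * 1e5)))

  expect_error(sigmaThreshold(DensityMap(array(1, c(2, 2, 2)))),
               class = "ligandblob_degenerate_error")
})

test_that("zero-inflation trimming drops the half-SD window about the median", {
  # median 0, population SD 4: only the 10 survives
  expect_identical(trimZeroInflation(c(0, 0, 0, 0, 10)), 10)

  sym <- c(-3, -2, -1, 0, 1, 2, 3)
  kept <- trimZeroInflation(sym)
  expect_setequal(kept, -kept)  # both tails retained, symmetric

  expect_error(trimZeroInflation(rep(2, 10)),
               class = "ligandblob_degenerate_error")
  expect_error(trimZeroInflation(3), class = "ligandblob_validation_error")

  # property: nothing inside the window survives, nothing outside is lost
  set.seed(4)
  for (rep in 1:20) {
    x <- c(rnorm(500), rep(0, sample(50:400, 1)))
    m <- median(x)
    s <- sqrt(mean((x - mean(x))^2))
    kept <- trimZeroInflation(x)
    expect_true(all(abs(kept - m) > 0.5 * s))
    expect_equal(sort(kept), sort(x[abs(x - m) > 0.5 * s]))
  }
})

test_that("quantile threshold matches the sort-based oracle", {
  expect_equal(round(pnorm(2.8), 4), 0.9974)
  expect_equal(thresholdValue(quantileThreshold(1:1000, q = 0.5)), 500.5)
  expect_equal(thresholdValue(quantileThreshold(rep(7, 5), q = 0.9)), 7)
  expect_error(quantileThreshold(1:10, q = 1.2),
               class = "ligandblob_validation_error")
  expect_error(quantileThreshold(numeric()),
               class = "ligandblob_validation_error")

  set.seed(5)
  for (n in c(10, 1e3, 1e5)) {
    x <- rnorm(n)
    for (q in c(0.1, 0.5, 0.9974, pnorm(2.8))) {
      expect_equal(thresholdValue(quantileThreshold(x, q)),
                   quantileSortOracle(x, q), tolerance = 1e-12)
    }
  }
  # monotonicity: raising q never lowers the threshold
  x <- rnorm(2000)
  qs <- seq(0.05, 0.99, by = 0.05)
  thr <- vapply(qs, function(q) thresholdValue(quantileThreshold(x, q)),
                numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("density cutoff zeroes below and preserves above the threshold", {
  g <- VoxelGrid(array(c(1, 2, 3, 4), c(4, 1, 1)))
  expect_identical(as.vector(gridValues(applyDensityCutoff(g, 2.5))),
                   c(0, 0, 3, 4))
  expect_identical(gridValues(applyDensityCutoff(g, 0)), gridValues(g))
  expect_true(all(gridValues(applyDensityCutoff(g, 99)) == 0))

  # raising the threshold never increases the surviving voxel count
  set.seed(6)
  v <- array(abs(rnorm(1000)), c(10, 10, 10))
  counts <- vapply(seq(0, 3, by = 0.25), function(thr)
    sum(gridValues(applyDensityCutoff(VoxelGrid(v), thr)) > 0), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("calibration rescaling pins the minimum nonzero value", {
  tab <- CalibrationTable(c(1, 2, 3), c(2, 1, 0.5))
  g <- VoxelGrid(array(c(0, 2, 4), c(3, 1, 1)))
  expect_identical(as.vector(gridValues(rescaleToCalibration(g, 2, tab))),
                   c(0, 1, 2))
  already <- VoxelGrid(array(c(0, 1, 9), c(3, 1, 1)))
  expect_identical(gridValues(rescaleToCalibration(already, 2, tab)),
                   gridValues(already))
  expect_error(rescaleToCalibration(VoxelGrid(array(0, c(2, 2, 2))), 2, tab),
               class = "ligandblob_degenerate_error")
  # resolutions outside the table clamp to the nearest bin
  expect_equal(calibrationTarget(tab, 0.2), 2)
  expect_equal(calibrationTarget(tab, 9), 0.5)
})

test_that("cryoEM normalization keeps blob cores and kills background", {
  fix <- recoveryFixture(seed = 5, snr = 8)
  tab <- makeCalibrationTable()
  nc <- normalizeCryoemMap(fix$map, resolution = 2.0, tab)
  vals <- gridValues(fix$map)
  out <- gridValues(nc$grid)

  truth <- unlist(fix$truthMasks)
  background <- setdiff(which(vals != 0), truth)
  expect_gt(mean(out[background] == 0), 0.99)

  # the high-density core of each blob survives the cutoff
  for (mask in fix$truthMasks) {
    core <- mask[vals[mask] >= 0.8 * max(vals[mask])]
    expect_true(all(out[core] > 0))
  }
  # provenance: quantile method with the 2.8-sigma-equivalent probability
  expect_identical(nc$threshold@method, "quantile")
  expect_equal(thresholdStats(nc$threshold)[["q"]], pnorm(2.8))
  expect_gt(nc$threshold@trimmedFraction, 0.5)
})

test_that("the normalization is invariant to the zero-inflation fraction", {
  # Construction in which invariance is exact: the nonzero content (a
  # symmetric bimodal background well clear of zero, plus one blob) is held
  # fixed while the amount of zero padding varies - the same particle in
  # differently sized solvent-masked boxes. The trim window always covers
  # the zero spike and never reaches the nonzero values, so the retained
  # sample - hence threshold and surviving voxels - is identical for every
  # zero-inflation fraction.
  set.seed(7)
  nNZ <- 20000L
  content <- sample(c(-1, 1), nNZ, replace = TRUE) * runif(nNZ, 2, 3)
  content[sample(nNZ, 300)] <- runif(300, 5, 8)

  selected <- list()
  thresholds <- numeric()
  for (f in c(0.1, 0.4, 0.8)) {
    nZero <- round(nNZ * f / (1 - f))
    vals <- c(content, numeric(nZero))
    m <- DensityMap(array(vals, c(length(vals), 1L, 1L)),
                    sourceKind = "cryoem_diff")
    nc <- normalizeCryoemMap(m, 2.0, makeCalibrationTable())
    expect_gte(nc$threshold@trimmedFraction, f * 0.99)  # spike is trimmed
    selected[[as.character(f)]] <-
      intersect(which(gridValues(nc$grid) > 0), seq_len(nNZ))
    thresholds <- c(thresholds, thresholdValue(nc$threshold))
  }
  expect_identical(selected[["0.1"]], selected[["0.4"]])
  expect_identical(selected[["0.1"]], selected[["0.8"]])
  expect_equal(max(thresholds) - min(thresholds), 0)
})

test_that("the normalization is scale invariant", {
  fix <- recoveryFixture(seed = 9, snr = 6, box = c(44L, 44L, 44L))
  tab <- makeCalibrationTable()
  base <- normalizeCryoemMap(fix$map, 2.0, tab)
  for (c0 in c(7.3, 0.01, 250)) {
    scaled <- DensityMap(gridValues(fix$map) * c0,
                         spacing = gridSpacing(fix$map),
                         origin = gridOrigin(fix$map),
                         sourceKind = "cryoem_diff")
    nc <- normalizeCryoemMap(scaled, 2.0, tab)
    expect_identical(which(gridValues(nc$grid) > 0),
                     which(gridValues(base$grid) > 0))
    expect_equal(gridValues(nc$grid), gridValues(base$grid),
                 tolerance = 1e-9)
  }
})

test_that("trimming raises the quantile threshold on zero-inflated maps", {
  fix <- recoveryFixture(seed = 13, snr = 6, box = c(44L, 44L, 44L))
  vals <- as.vector(gridValues(fix$map))
  withTrim <- thresholdValue(quantileThreshold(trimZeroInflation(vals)))
  withoutTrim <- thresholdValue(quantileThreshold(vals))
  expect_gt(withTrim, withoutTrim)
})
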