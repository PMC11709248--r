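# Classifier contracts: score normalization, invariances, gradients,
# imbalance handling and learnability.

test_that("configs validate their key constraints", {
  expect_error(modelConfig("riconvpp", nClasses = 1),
               class = "ligandblob_validation_error")
  expect_error(modelConfig("riconvpp", nClasses = 3,
                           riconvChannels = c(8L, 8L)),
               class = "ligandblob_validation_error")
  expect_error(trainConfig(epochs = 0),
               class = "ligandblob_validation_error")
  cfg <- modelConfig("riconvpp", nClasses = 5)
  expect_identical(cfg$riconvLayers, 5L)   # five invariant conv layers
  expect_identical(cfg$fcLayers, 2L)       # two fully connected head layers
})

test_that("untrained models produce uniform, normalized, deterministic scores", {
  set.seed(51)
  cloud <- randomCloud(40)
  for (make in list(tinyRiconvConfig, tinyMinklocConfig)) {
    model <- buildModel(make(4), seed = 3)
    p <- predictLigand(model, cloud)
    expect_equal(unname(classScores(p)), rep(0.25, 4))   # zero-init head
    expect_equal(sum(classScores(p)), 1, tolerance = 1e-9)
    expect_identical(rankedLabels(p), model@labels)      # ties by class order

    model <- randomizeHead(model, seed = 4)
    p1 <- predictLigand(model, cloud)
    p2 <- predictLigand(model, cloud)
    expect_identical(classScores(p1), classScores(p2))
    expect_true(all(classScores(p1) >= 0))
    expect_equal(sum(classScores(p1)), 1, tolerance = 1e-9)
    sc <- classScores(p1)[rankedLabels(p1)]
    expect_true(all(diff(sc) <= 1e-12))                  # ranking sorted

    expect_error(predictLigand(model, PointCloud(matrix(0, 0, 4))),
                 class = "ligandblob_degenerate_error")
  }
})

test_that("the invariant-convolution network is rotation invariant", {
  set.seed(52)
  model <- randomizeHead(buildModel(tinyRiconvConfig(4), seed = 5), seed = 6)
  worst <- 0
  for (ci in 1:10) {
    cloud <- randomCloud(30)
    base <- classScores(predictLigand(model, cloud))
    for (ri in 1:20) {
      rot <- classScores(predictLigand(model,
                                       rotateCloud(cloud,
                                                   randomRotationMatrix())))
      worst <- max(worst, max(abs(base - rot)))
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("both networks are invariant to point order; the sparse network is
          equivariant to aligned translations", {
  set.seed(53)
  cloud <- randomCloud(50)
  pts <- cloudPoints(cloud)
  perm <- sample(nrow(pts))
  shuffled <- PointCloud(pts[perm, , drop = FALSE])

  riconv <- randomizeHead(buildModel(tinyRiconvConfig(4), seed = 7), seed = 8)
  expect_lt(max(abs(classScores(predictLigand(riconv, cloud)) -
                      classScores(predictLigand(riconv, shuffled)))), 1e-5)

  mink <- randomizeHead(buildModel(tinyMinklocConfig(4), seed = 9), seed = 10)
  expect_lt(max(abs(classScores(predictLigand(mink, cloud)) -
                      classScores(predictLigand(mink, shuffled)))), 1e-5)

  # translation by a stride-aligned multiple of the quantization size
  q <- mink@config$quantizationSize
  moved <- PointCloud(cbind(pts[, 1:3] + 4 * q, pts[, 4]))
  expect_lt(max(abs(classScores(predictLigand(mink, cloud)) -
                      classScores(predictLigand(mink, moved)))), 1e-4)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(54)
  ds <- makeShapeDataset(nClasses = 3, nPerClass = 1, nPoints = 20, seed = 3)
  lb <- asNamespace("ligandblob")
  for (make in list(tinyRiconvConfig, tinyMinklocConfig)) {
    model <- randomizeHead(buildModel(make(3), seed = 11), seed = 12)
    prep <- lb$prepareCloud(ds$clouds[[1]], model@config)
    lossOf <- function() {
      fw <- lb$forwardLogits(model, prep)
      lid <- lb$adCrossEntropy(fw$tape, fw$id, 2L)
      list(fw = fw, lid = lid, val = lb$tapeVal(fw$tape, lid)[1, 1])
    }
    r <- lossOf()
    grads <- lb$paramGrads(r$fw$tape, lb$backward(r$fw$tape, r$lid))
    for (nm in names(grads)) {
      W <- get(nm, model@params)
      i <- sample(length(W), 1)
      eps <- 1e-5
      W2 <- W; W2[i] <- W[i] + eps; assign(nm, W2, model@params)
      up <- lossOf()$val
      W2[i] <- W[i] - eps; assign(nm, W2, model@params)
      dn <- lossOf()$val
      assign(nm, W, model@params)
      num <- (up - dn) / (2 * eps)
      # tolerance covers central-difference truncation error; genuine
      # gradient bugs show up as O(1) relative disagreement
      expect_lt(abs(num - grads[[nm]][i]) /
                  max(1e-6, abs(num) + abs(grads[[nm]][i])), 1e-4)
    }
  }
})

test_that("training decreases the loss and handles imbalance schemes", {
  ds <- makeShapeDataset(nClasses = 3, nPerClass = 12, nPoints = 24, seed = 13)
  model <- buildModel(tinyRiconvConfig(3),
                      labels = sort(unique(ds$labels)), seed = 14)
  trainModel(model, ds$clouds, ds$labels,
             trainConfig(learningRate = 0.01, epochs = 5, seed = 15))
  h <- model@state$history
  expect_lt(h$loss[5], h$loss[1])

  # oversampling: per-epoch class exposures equal within 5% on a 10:1 set
  idx <- c(1:20, 21:22)   # 20 of class 1, 2 of class 2
  ds2 <- makeShapeDataset(nClasses = 2, nPerClass = 20, nPoints = 16,
                          seed = 16)
  labs <- ds2$labels[idx]
  model2 <- buildModel(tinyRiconvConfig(2), labels = sort(unique(labs)),
                       seed = 17)
  trainModel(model2, ds2$clouds[idx], labs,
             trainConfig(learningRate = 0.01, epochs = 2, seed = 18,
                         samplingScheme = "oversample", valFraction = 0))
  expo <- model2@state$exposure
  expect_true(all(abs(expo[, 1] - expo[, 2]) / pmax(expo[, 1], expo[, 2])
                  <= 0.05))

  # undersampling caps the majority class at the minority count
  model3 <- buildModel(tinyRiconvConfig(2), labels = sort(unique(labs)),
                       seed = 19)
  trainModel(model3, ds2$clouds[idx], labs,
             trainConfig(learningRate = 0.01, epochs = 1, seed = 20,
                         samplingScheme = "undersample", valFraction = 0))
  expect_identical(unname(model3@state$exposure[1, 1]),
                   unname(model3@state$exposure[1, 2]))

  expect_error(trainModel(model, ds$clouds[1:5], rep("line", 5),
                          trainConfig(epochs = 1)),
               class = "ligandblob_validation_error")
})

test_that("the sparse-voxel network also learns (loss decreases)", {
  ds <- makeShapeDataset(nClasses = 3, nPerClass = 10, nPoints = 24, seed = 21)
  model <- buildModel(tinyMinklocConfig(3),
                      labels = sort(unique(ds$labels)), seed = 22)
  trainModel(model, ds$clouds, ds$labels,
             trainConfig(learningRate = 0.01, epochs = 5, seed = 23))
  h <- model@state$history
  expect_lt(h$loss[5], h$loss[1])
})

test_that("the network can memorize a small training set", {
  ds <- makeShapeDataset(nClasses = 5, nPerClass = 10, nPoints = 24, seed = 24)
  model <- buildModel(tinyRiconvConfig(5),
                      labels = sort(unique(ds$labels)), seed = 25)
  acc <- 0
  for (round in 1:20) {   # up to 200 epochs in chunks of 10
    trainModel(model, ds$clouds, ds$labels,
               trainConfig(learningRate = 0.01, epochs = 10,
                           seed = 26 + round, valFraction = 0))
    preds <- vapply(ds$clouds, function(cl)
      rankedLabels(predictLigand(model, cl))[1], character(1))
    acc <- mean(preds == ds$labels)
    if (acc == 1) break
  }
  expect_identical(acc, 1)
})

test_that("training is reproducible for a fixed seed", {
  ds <- makeShapeDataset(nClasses = 3, nPerClass = 8, nPoints = 16, seed = 27)
  run <- function() {
    m <- buildModel(tinyRiconvConfig(3), labels = sort(unique(ds$labels)),
                    seed = 28)
    trainModel(m, ds$clouds, ds$labels,
               trainConfig(learningRate = 0.01, epochs = 3, seed = 29))
    m@state$history
  }
  expect_identical(run(), run())
})
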