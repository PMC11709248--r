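# Model configuration, construction, training and prediction.

#' Model configuration
#'
#' @param architecture "riconvpp" (rotation-invariant point convolutions) or
#'   "minkloc" (sparse-voxel feature pyramid with NetVLAD).
#' @param nClasses number of ligand groups (>= 2).
#' @param riconvLayers number of invariant convolution layers (default 5).
#' @param fcLayers number of fully connected head layers (default 2).
#' @param riconvChannels channel width per invariant convolution layer;
#'   length must equal \code{riconvLayers}.
#' @param fcHidden width of the hidden fully connected layer.
#' @param neighborhoodK neighborhood size for the local reference axes and
#'   invariant convolutions (default 16).
#' @param quantizationSize sparse voxel edge in Angstrom (default 0.2, one
#'   canonical voxel).
#' @param channels channel widths of the three bottom-up convolution blocks.
#' @param fusedChannels width of the fused top-down feature maps.
#' @param netvladClusters number of NetVLAD clusters (default 32).
#' @param ecaKernel channel-attention kernel width (odd; default 3).
#' @return A validated config list.
#' @export
modelConfig <- function(architecture = c("riconvpp", "minkloc"),
                        nClasses,
                        riconvLayers = 5L, fcLayers = 2L,
                        riconvChannels = c(32L, 32L, 64L, 64L, 128L),
                        fcHidden = 128L,
                        neighborhoodK = 16L,
                        quantizationSize = 0.2,
                        channels = c(32L, 64L, 128L),
                        fusedChannels = 64L,
                        netvladClusters = 32L,
                        ecaKernel = 3L) {
  architecture <- match.arg(architecture)
  if (nClasses < 2L) lbValidationError("nClasses must be >= 2")
  if (length(riconvChannels) != riconvLayers)
    lbValidationError("riconvChannels must have one width per layer")
  if (length(channels) != 3L)
    lbValidationError("channels must give widths for 3 convolution blocks")
  if (ecaKernel != 3L)
    lbValidationError("only the default channel-attention kernel (3) is implemented")
  list(architecture = architecture, nClasses = as.integer(nClasses),
       riconvLayers = as.integer(riconvLayers), fcLayers = as.integer(fcLayers),
       riconvChannels = as.integer(riconvChannels),
       fcHidden = as.integer(fcHidden),
       neighborhoodK = as.integer(neighborhoodK),
       quantizationSize = quantizationSize,
       channels = as.integer(channels),
       fusedChannels = as.integer(fusedChannels),
       netvladClusters = as.integer(netvladClusters),
       ecaKernel = as.integer(ecaKernel))
}

#' Training configuration
#'
#' @param learningRate Adam step size.
#' @param gradAccumulationBatches number of clouds whose gradients are
#'   accumulated before each optimizer step.
#' @param samplingScheme class-imbalance handling: "none", "undersample"
#'   (cap majority classes at the minority count per epoch) or "oversample"
#'   (duplicate minority examples within each epoch up to the majority
#'   count).
#' @param epochs number of passes over the training portion.
#' @param seed RNG seed controlling initialization order, shuffling and
#'   resampling; fixed for reproducibility.
#' @param valFraction fraction of the dataset held out (stratified) as the
#'   validation set tracked in the history.
#' @return A validated config list.
#' @export
trainConfig <- function(learningRate = 0.01, gradAccumulationBatches = 8L,
                        samplingScheme = c("none", "undersample", "oversample"),
                        epochs = 30L, seed = 1L, valFraction = 0.2) {
  samplingScheme <- match.arg(samplingScheme)
  if (epochs < 1L) lbValidationError("epochs must be >= 1")
  list(learningRate = learningRate,
       gradAccumulationBatches = as.integer(gradAccumulationBatches),
       samplingScheme = samplingScheme, epochs = as.integer(epochs),
       seed = as.integer(seed), valFraction = valFraction)
}

glorotMatrix <- function(shape) {
  if (shape[1] == 1L && shape[2] == 1L) return(matrix(0.5, 1, 1))
  sd <- sqrt(2 / sum(shape))
  matrix(stats::rnorm(prod(shape), sd = sd), shape[1], shape[2])
}

#' Build an untrained ligand classifier
#'
#' Weights are Glorot-initialized except the final classification layer,
#' which starts at zero so an untrained model outputs uniform scores.
#'
#' @param cfg a \code{\link{modelConfig}}.
#' @param labels class labels; defaults to "g1".."gK".
#' @param seed RNG seed for weight initialization.
#' @return A \linkS4class{LigandClassifier}.
#' @export
buildModel <- function(cfg, labels = NULL, seed = 1) {
  if (is.null(labels)) labels <- sprintf("g%d", seq_len(cfg$nClasses))
  if (length(labels) != cfg$nClasses)
    lbValidationError("labels must match nClasses")
  shapes <- if (cfg$architecture == "riconvpp") riconvParamShapes(cfg)
            else minklocParamShapes(cfg)
  params <- new.env(parent = emptyenv())
  withSeed(seed, {
    for (name in names(shapes)) {
      sh <- shapes[[name]]
      val <- if (name %in% c("Wfc2", "bfc2", "Wout", "bout")) {
        matrix(0, sh[1], sh[2])                    # uniform initial scores
      } else if (grepl("^(g|gc)[0-9]", name)) {
        matrix(1, sh[1], sh[2])                    # normalization scale
      } else if (grepl("^(b|h|bc|hc|ba)", name)) {
        matrix(0, sh[1], sh[2])
      } else if (name == "Cm") {
        matrix(stats::rnorm(prod(sh), sd = 0.1), sh[1], sh[2])
      } else glorotMatrix(sh)
      assign(name, val, envir = params)
    }
  })
  state <- new.env(parent = emptyenv())
  state$trained <- FALSE
  state$history <- NULL
  new("LigandClassifier", config = cfg, params = params, state = state,
      labels = as.character(labels))
}

prepareCloud <- function(cloud, cfg) {
  if (nrow(cloudPoints(cloud)) == 0L)
    lbDegenerateError("empty point cloud")
  if (cfg$architecture == "riconvpp") prepareRiconvInput(cloud, cfg)
  else prepareMinklocInput(cloud, cfg)
}

forwardLogits <- function(model, prep) {
  tp <- tapeNew()
  id <- if (model@config$architecture == "riconvpp")
    riconvForward(tp, model@params, prep, model@config)
  else
    minklocForward(tp, model@params, prep, model@config)
  list(tape = tp, id = id, logits = as.vector(tapeVal(tp, id)))
}

# per-epoch example stream under the configured imbalance scheme
epochIndices <- function(labels, scheme) {
  byClass <- split(seq_along(labels), labels)
  sizes <- lengths(byClass)
  idx <- switch(scheme,
    none = seq_along(labels),
    undersample = unlist(lapply(byClass, function(ix)
      if (length(ix) > min(sizes)) sample(ix, min(sizes)) else ix)),
    oversample = unlist(lapply(byClass, function(ix)
      if (length(ix) < max(sizes))
        c(ix, sample(ix, max(sizes) - length(ix), replace = TRUE))
      else ix)))
  sample(idx)   # shuffle
}

#' Train a ligand classifier
#'
#' Minimizes cross-entropy with Adam, accumulating gradients over
#' \code{gradAccumulationBatches} clouds per step. A stratified fraction of
#' the data is held out for per-epoch validation accuracy. Training is
#' deterministic for a fixed seed.
#'
#' @param model a \linkS4class{LigandClassifier} from \code{\link{buildModel}}.
#' @param clouds list of \linkS4class{PointCloud} objects.
#' @param labels class label per cloud (must match the model's label set).
#' @param cfg a \code{\link{trainConfig}}.
#' @return The trained model (weights updated in place); the training
#'   history is in \code{model@state$history} (epoch, loss, valAccuracy).
#' @export
trainModel <- function(model, clouds, labels, cfg = trainConfig()) {
  stopifnot(is(model, "LigandClassifier"))
  labels <- as.character(labels)
  if (length(clouds) != length(labels))
    lbValidationError("one label per cloud required")
  if (length(unique(labels)) < 2L)
    lbValidationError("at least 2 classes must be present for training")
  if (!all(labels %in% model@labels))
    lbValidationError("labels outside the model's label space")
  y <- match(labels, model@labels)

  preps <- lapply(clouds, prepareCloud, cfg = model@config)

  withSeed(cfg$seed, {
    # stratified validation split
    valIdx <- unlist(lapply(split(seq_along(y), y), function(ix) {
      nv <- floor(length(ix) * cfg$valFraction)
      if (nv >= 1L) sample(ix, nv) else integer()
    }))
    trainIdx <- setdiff(seq_along(y), valIdx)
    if (length(valIdx) == 0L) valIdx <- trainIdx

    opt <- adamInit()
    history <- data.frame(epoch = integer(), loss = numeric(),
                          valAccuracy = numeric())
    exposure <- integer(0)
    # same-shape riconv clouds can share a forward pass (batched matmuls);
    # the sparse-voxel network runs cloud by cloud
    batchable <- model@config$architecture == "riconvpp"
    key <- if (batchable)
      vapply(preps, function(p) sprintf("%d/%d", p$n, p$k), character(1))
    else as.character(seq_along(preps))
    for (ep in seq_len(cfg$epochs)) {
      stream <- trainIdx[epochIndices(y[trainIdx], cfg$samplingScheme)]
      exp_ep <- tabulate(y[stream], nbins = model@config$nClasses)
      exposure <- rbind(exposure, exp_ep)
      losses <- numeric(0)
      chunks <- split(stream, ceiling(seq_along(stream) /
                                        cfg$gradAccumulationBatches))
      for (chunk in chunks) {
        acc <- NULL
        for (sub in split(chunk, key[chunk])) {
          if (batchable) {
            bp <- stackRiconvPreps(preps[sub])
            fw <- forwardLogits(model, bp)
            lossId <- adCrossEntropyRows(fw$tape, fw$id, y[sub])
            losses <- c(losses, rep(tapeVal(fw$tape, lossId)[1, 1],
                                    length(sub)))
            grads <- paramGrads(fw$tape, backward(fw$tape, lossId))
            acc <- accumulateScaled(acc, grads, length(sub))
          } else {
            for (i in sub) {
              fw <- forwardLogits(model, preps[[i]])
              lossId <- adCrossEntropy(fw$tape, fw$id, y[i])
              losses <- c(losses, tapeVal(fw$tape, lossId)[1, 1])
              grads <- paramGrads(fw$tape, backward(fw$tape, lossId))
              acc <- accumulateScaled(acc, grads, 1)
            }
          }
        }
        adamStep(model@params, opt, acc, length(chunk), cfg$learningRate)
      }

      predVal <- predictClassIndices(model, preps[valIdx], key[valIdx],
                                     batchable)
      history <- rbind(history,
                       data.frame(epoch = ep, loss = mean(losses),
                                  valAccuracy = mean(predVal == y[valIdx])))
    }
    model@state$history <- history
    model@state$exposure <- exposure
    model@state$trained <- TRUE
  })
  invisible(model)
}

# argmax with ties broken towards the smallest index
which.max2 <- function(x) which(x == max(x))[1]

accumulateScaled <- function(a, b, w) {
  if (is.null(a)) a <- list()
  for (name in names(b)) {
    g <- b[[name]] * w
    a[[name]] <- if (is.null(a[[name]])) g else a[[name]] + g
  }
  a
}

# argmax class per prepared cloud (ties to the smallest index); riconv preps
# of equal shape share one batched forward pass
predictClassIndices <- function(model, preps, keys, batchable,
                                batchSize = 64L) {
  out <- integer(length(preps))
  if (batchable) {
    for (sub in split(seq_along(preps), keys)) {
      for (part in split(sub, ceiling(seq_along(sub) / batchSize))) {
        bp <- stackRiconvPreps(preps[part])
        fw <- forwardLogits(model, bp)
        L <- matrix(fw$logits, nrow = length(part))
        out[part] <- apply(L, 1, which.max2)
      }
    }
  } else {
    for (i in seq_along(preps)) {
      fw <- forwardLogits(model, preps[[i]])
      out[i] <- which.max2(fw$logits)
    }
  }
  out
}

adamInit <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adamStep <- function(params, opt, grads, nAcc, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (name in names(grads)) {
    g <- grads[[name]] / nAcc
    m <- opt$m[[name]] %||% (g * 0)
    v <- opt$v[[name]] %||% (g * 0)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    opt$m[[name]] <- m; opt$v[[name]] <- v
    mh <- m / (1 - beta1^opt$t)
    vh <- v / (1 - beta2^opt$t)
    assign(name, get(name, envir = params) - lr * mh / (sqrt(vh) + eps),
           envir = params)
  }
}

#' Predict the ligand group of a point cloud
#'
#' @param model a \linkS4class{LigandClassifier}.
#' @param cloud a non-empty \linkS4class{PointCloud}.
#' @return A \linkS4class{PredictionResult} with the full score vector and
#'   the complete descending ranking (ties broken by class order).
#' @export
predictLigand <- function(model, cloud) {
  stopifnot(is(model, "LigandClassifier"))
  prep <- prepareCloud(cloud, model@config)
  fw <- forwardLogits(model, prep)
  p <- softmaxVector(fw$logits)
  names(p) <- model@labels
  ord <- order(-p, seq_along(p))
  new("PredictionResult", classScores = p,
      rankedLabels = model@labels[ord])
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint stores the configuration, label map and weights.
#'
#' @param model a \linkS4class{LigandClassifier}.
#' @param path checkpoint path (.rds).
#' @return \code{path} invisibly / the restored classifier.
#' @export
saveClassifier <- function(model, path) {
  saveRDS(list(config = model@config, labels = model@labels,
               params = as.list(model@params)), path)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  ck <- readRDS(path)
  params <- list2env(ck$params, parent = emptyenv())
  state <- new.env(parent = emptyenv())
  state$trained <- TRUE
  new("LigandClassifier", config = ck$config, params = params,
      state = state, labels = ck$labels)
}
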