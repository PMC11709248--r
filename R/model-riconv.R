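# Rotation-invariant point-convolution classifier.
#
# Each point gets a local reference axis (LRA) from its neighborhood
# covariance, sign-fixed towards the cloud centroid; all neighborhood
# features are built from distances and dot products of LRAs and offsets,
# so they are exactly invariant under rigid rotation of the cloud. Five
# stacked invariant convolution layers (shared MLP over each point's k
# neighbors followed by max-pooling over the neighborhood), each with
# batch-style normalization and ReLU, feed symmetric global pooling and two
# fully connected layers with a softmax over the ligand groups.

N_GEO_FEATURES <- 7L

riconvParamShapes <- function(cfg) {
  ch <- cfg$riconvChannels
  shapes <- list()
  inDim <- N_GEO_FEATURES
  for (l in seq_along(ch)) {
    shapes[[sprintf("W%d", l)]] <- c(inDim, ch[l])
    shapes[[sprintf("b%d", l)]] <- c(1L, ch[l])
    shapes[[sprintf("g%d", l)]] <- c(1L, ch[l])
    shapes[[sprintf("h%d", l)]] <- c(1L, ch[l])
    inDim <- ch[l] + N_GEO_FEATURES   # next layer sees features + geometry
  }
  last <- ch[length(ch)]
  shapes$Wfc1 <- c(2L * last, cfg$fcHidden)
  shapes$bfc1 <- c(1L, cfg$fcHidden)
  shapes$Wfc2 <- c(cfg$fcHidden, cfg$nClasses)
  shapes$bfc2 <- c(1L, cfg$nClasses)
  shapes
}

# prep may describe a single cloud (B = 1) or a stack of B same-sized clouds
# (see stackRiconvPreps); rows stay grouped (cloud, point, neighbor), so the
# neighborhood max-pool and the per-cloud global pools remain regular.
riconvForward <- function(tp, params, prep, cfg) {
  ch <- cfg$riconvChannels
  k <- prep$k
  B <- prep$B %||% 1L
  n <- prep$n
  geo <- adConst(tp, prep$geo)
  h <- NULL
  for (l in seq_along(ch)) {
    x <- if (l == 1L) geo else
      adConcatCols(tp, adGatherRows(tp, h, prep$nnFlat), geo)
    z <- adAddBias(tp, adMM(tp, x, adParam(tp, params, sprintf("W%d", l))),
                   adParam(tp, params, sprintf("b%d", l)))
    z <- adFeatNormGroups(tp, z, rep(seq_len(B), each = n * k), B)
    z <- adAddBias(tp, adColScale(tp, z, adParam(tp, params, sprintf("g%d", l))),
                   adParam(tp, params, sprintf("h%d", l)))
    z <- adRelu(tp, z)
    h <- adMaxPoolRegular(tp, z, k)
  }
  gmax <- adMaxPoolRegular(tp, h, n)                 # B x C per-cloud max
  gmean <- adScale(tp, adPoolSum(tp, h, rep(seq_len(B), each = n), B), 1 / n)
  glob <- adConcatCols(tp, gmax, gmean)
  f1 <- adRelu(tp, adAddBias(tp, adMM(tp, glob, adParam(tp, params, "Wfc1")),
                             adParam(tp, params, "bfc1")))
  adAddBias(tp, adMM(tp, f1, adParam(tp, params, "Wfc2")),
            adParam(tp, params, "bfc2"))
}

# stack same-shape riconv preps into one batch prep (rows block-diagonal)
stackRiconvPreps <- function(preps) {
  B <- length(preps)
  if (B == 1L) return(c(preps[[1]], list(B = 1L)))
  n <- preps[[1]]$n; k <- preps[[1]]$k
  nnFlat <- unlist(lapply(seq_len(B), function(b)
    preps[[b]]$nnFlat + (b - 1L) * n))
  geo <- do.call(rbind, lapply(preps, `[[`, "geo"))
  list(n = n, k = k, nnFlat = nnFlat, geo = geo, B = B)
}
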