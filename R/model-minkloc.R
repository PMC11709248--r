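# Sparse-voxel feature-pyramid classifier.
#
# The cloud is quantized into sparse voxels carrying density as the single
# input feature. A bottom-up pathway of three sparse 3x3x3 convolution
# blocks with increasing receptive fields (stride-2 pooling between levels),
# each with batch-style normalization, ReLU and an Efficient Channel
# Attention gate, produces a pyramid of feature maps; a top-down pathway
# projects coarser maps back and adds them to the finer levels (transposed
# convolution realized as parent-lookup upsampling plus a 1x1 projection).
# The fused local features are aggregated into a global descriptor with
# NetVLAD (soft-assigned cluster residuals) and classified linearly with a
# softmax.

minklocParamShapes <- function(cfg) {
  ch <- cfg$channels           # e.g. c(32, 64, 128)
  fuse <- cfg$fusedChannels
  K <- cfg$netvladClusters
  shapes <- list()
  inDim <- 1L
  for (l in seq_along(ch)) {
    shapes[[sprintf("Wc%d", l)]] <- c(27L * inDim, ch[l])
    shapes[[sprintf("bc%d", l)]] <- c(1L, ch[l])
    shapes[[sprintf("gc%d", l)]] <- c(1L, ch[l])
    shapes[[sprintf("hc%d", l)]] <- c(1L, ch[l])
    for (w in c("A", "B", "C"))
      shapes[[sprintf("eca%d%s", l, w)]] <- c(1L, 1L)
    inDim <- ch[l]
  }
  shapes$Wl1 <- c(ch[1], fuse)        # lateral 1x1 projections
  shapes$Wl2 <- c(ch[2], fuse)
  shapes$Wt3 <- c(ch[3], fuse)        # top-down projections
  shapes$Wt2 <- c(fuse, fuse)
  shapes$Wa <- c(fuse, K)             # NetVLAD soft-assignment
  shapes$ba <- c(1L, K)
  shapes$Cm <- c(K, fuse)             # NetVLAD cluster centers
  shapes$Wout <- c(K * fuse, cfg$nClasses)
  shapes$bout <- c(1L, cfg$nClasses)
  shapes
}

sparseConv3 <- function(tp, h, nbr, params, wName) {
  gathered <- NULL
  for (o in seq_len(ncol(nbr))) {
    g <- adGatherRows(tp, h, nbr[, o])
    gathered <- if (is.null(gathered)) g else adConcatCols(tp, gathered, g)
  }
  adMM(tp, gathered, adParam(tp, params, wName))
}

ecaGate <- function(tp, h, params, level) {
  s <- adGlobalMean(tp, h)
  y <- adAdd(tp,
             adSMul(tp, adShiftCols(tp, s, 1L),
                    adParam(tp, params, sprintf("eca%dA", level))),
             adSMul(tp, s, adParam(tp, params, sprintf("eca%dB", level))))
  y <- adAdd(tp, y,
             adSMul(tp, adShiftCols(tp, s, -1L),
                    adParam(tp, params, sprintf("eca%dC", level))))
  adColScale(tp, h, adSigmoid(tp, y))
}

minklocForward <- function(tp, params, prep, cfg) {
  lv <- prep$levels
  h <- adConst(tp, prep$feat)
  acts <- list()
  for (l in seq_along(cfg$channels)) {
    z <- adAddBias(tp, sparseConv3(tp, h, lv[[l]]$nbr, params,
                                   sprintf("Wc%d", l)),
                   adParam(tp, params, sprintf("bc%d", l)))
    z <- adFeatNorm(tp, z)
    z <- adAddBias(tp, adColScale(tp, z, adParam(tp, params, sprintf("gc%d", l))),
                   adParam(tp, params, sprintf("hc%d", l)))
    z <- adRelu(tp, z)
    z <- ecaGate(tp, z, params, l)
    acts[[l]] <- z
    if (l < length(cfg$channels))
      h <- adMeanPoolGroups(tp, z, lv[[l]]$parent, lv[[l]]$nCoarse)
  }

  # top-down: project level 3 onto level 2, then onto level 1
  l2 <- adAdd(tp, adMM(tp, acts[[2]], adParam(tp, params, "Wl2")),
              adMM(tp, adGatherRows(tp, acts[[3]], lv[[2]]$parent),
                   adParam(tp, params, "Wt3")))
  l1 <- adAdd(tp, adMM(tp, acts[[1]], adParam(tp, params, "Wl1")),
              adMM(tp, adGatherRows(tp, l2, lv[[1]]$parent),
                   adParam(tp, params, "Wt2")))
  local <- adRelu(tp, l1)

  # NetVLAD aggregation: V_k = sum_i a_ik (x_i - c_k)
  A <- adSoftmaxRows(tp, adAddBias(tp, adMM(tp, local, adParam(tp, params, "Wa")),
                                   adParam(tp, params, "ba")))
  S <- adMM(tp, adTranspose(tp, A), local)
  asum <- adTranspose(tp, adGlobalSum(tp, A))           # K x 1
  Cw <- adRowScale(tp, adParam(tp, params, "Cm"), asum)
  V <- adAdd(tp, S, adScale(tp, Cw, -1))
  V <- adRowNorm(tp, V)                                  # intra-normalization
  v <- adRowNorm(tp, adFlattenRow(tp, V))
  adAddBias(tp, adMM(tp, v, adParam(tp, params, "Wout")),
            adParam(tp, params, "bout"))
}
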