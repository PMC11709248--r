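# A minimal reverse-mode automatic differentiation tape over R matrices.
#
# Both classifiers are small enough that a dynamic tape of dense-matrix ops
# (BLAS-backed) trains them in reasonable time on one CPU. Every op stores a
# closure computing the vector-Jacobian products of its inputs; backward()
# walks the tape once in reverse. Values are plain numeric matrices.

tapeNew <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$paramIds <- list()
  tp
}

tapeNode <- function(tp, val, parents = integer(), vjp = NULL) {
  # promise args may append to the tape themselves; force them before
  # claiming this node's id
  force(val); force(parents); force(vjp)
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", tp$n))
  tp$nodes[[tp$n]] <- list(val = val, parents = parents, vjp = vjp)
  tp$n
}

tapeVal <- function(tp, id) {
  force(id)  # id promises may append to the tape; force before reading it
  tp$nodes[[id]]$val
}

# leaf for a constant (no gradient tracked)
adConst <- function(tp, v) tapeNode(tp, v)

# leaf for a parameter matrix; records name -> node id for gradient readout
adParam <- function(tp, params, name) {
  id <- tapeNode(tp, params[[name]])
  tp$paramIds[[name]] <- c(tp$paramIds[[name]], id)
  id
}

backward <- function(tp, rootId) {
  grads <- vector("list", tp$n)
  root <- tp$nodes[[rootId]]$val
  grads[[rootId]] <- array(1, dim = dim(root) %||% c(1L, 1L))
  for (i in rev(seq_len(rootId))) {
    g <- grads[[i]]
    node <- tp$nodes[[i]]
    if (is.null(g) || is.null(node$vjp)) next
    pg <- node$vjp(g)
    for (j in seq_along(node$parents)) {
      pid <- node$parents[j]
      if (is.null(pg[[j]])) next
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]]
                      else grads[[pid]] + pg[[j]]
    }
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

paramGrads <- function(tp, grads) {
  out <- list()
  for (name in names(tp$paramIds)) {
    for (id in tp$paramIds[[name]]) {
      g <- grads[[id]]
      if (is.null(g)) next
      out[[name]] <- if (is.null(out[[name]])) g else out[[name]] + g
    }
  }
  out
}

# ---- ops -------------------------------------------------------------------

adMM <- function(tp, a, b) {
  A <- tapeVal(tp, a); B <- tapeVal(tp, b)
  tapeNode(tp, A %*% B, c(a, b),
           function(G) list(G %*% t(B), t(A) %*% G))
}

adAdd <- function(tp, a, b) {
  tapeNode(tp, tapeVal(tp, a) + tapeVal(tp, b), c(a, b),
           function(G) list(G, G))
}

adScale <- function(tp, a, s) {
  tapeNode(tp, tapeVal(tp, a) * s, a, function(G) list(G * s))
}

# fast row-vector broadcast over a column-major matrix
expandRow <- function(v, m) rep(v, rep.int(m, length(v)))

adAddBias <- function(tp, a, b) {  # b: 1 x C bias row
  A <- tapeVal(tp, a); B <- tapeVal(tp, b)
  tapeNode(tp, A + expandRow(as.vector(B), nrow(A)), c(a, b),
           function(G) list(G, matrix(colSums(G), 1)))
}

adRelu <- function(tp, a) {
  A <- tapeVal(tp, a)
  mask <- A > 0
  tapeNode(tp, A * mask, a, function(G) list(G * mask))
}

adSigmoid <- function(tp, a) {
  S <- 1 / (1 + exp(-tapeVal(tp, a)))
  tapeNode(tp, S, a, function(G) list(G * S * (1 - S)))
}

adEwMul <- function(tp, a, b) {
  A <- tapeVal(tp, a); B <- tapeVal(tp, b)
  tapeNode(tp, A * B, c(a, b), function(G) list(G * B, G * A))
}

adColScale <- function(tp, a, g) {  # g: 1 x C per-channel gate
  A <- tapeVal(tp, a); gv <- as.vector(tapeVal(tp, g))
  ge <- expandRow(gv, nrow(A))
  tapeNode(tp, A * ge, c(a, g),
           function(G) list(G * ge, matrix(colSums(G * A), 1)))
}

adSMul <- function(tp, a, w) {  # w: 1 x 1 scalar parameter
  A <- tapeVal(tp, a); wv <- tapeVal(tp, w)[1, 1]
  tapeNode(tp, A * wv, c(a, w),
           function(G) list(G * wv, matrix(sum(G * A), 1, 1)))
}

adGatherRows <- function(tp, a, idx) {  # idx == 0 gathers a zero row
  A <- tapeVal(tp, a)
  nz <- idx > 0L
  out <- matrix(0, length(idx), ncol(A))
  out[nz, ] <- A[idx[nz], , drop = FALSE]
  tapeNode(tp, out, a, function(G) {
    dA <- matrix(0, nrow(A), ncol(A))
    if (any(nz)) {
      rs <- rowsum(G[nz, , drop = FALSE], group = idx[nz])
      dA[as.integer(rownames(rs)), ] <- rs
    }
    list(dA)
  })
}

# max over blocks of k consecutive rows (rows pre-grouped per neighborhood)
adMaxPoolRegular <- function(tp, a, k) {
  A <- tapeVal(tp, a)
  m <- nrow(A); n <- m %/% k; C <- ncol(A)
  rows1 <- seq(1L, m, by = k)
  cur <- A[rows1, , drop = FALSE]
  arg <- matrix(rows1, n, C)
  if (k > 1L) for (j in 1L:(k - 1L)) {
    rj <- rows1 + j
    Aj <- A[rj, , drop = FALSE]
    upd <- Aj > cur
    cur[upd] <- Aj[upd]
    arg[upd] <- matrix(rj, n, C)[upd]
  }
  tapeNode(tp, cur, a, function(G) {
    dA <- matrix(0, m, C)
    cells <- cbind(as.vector(arg), rep(seq_len(C), each = n))
    dA[cells] <- as.vector(G)
    list(dA)
  })
}

adGlobalMax <- function(tp, a) {  # 1 x C max over all rows
  A <- tapeVal(tp, a)
  C <- ncol(A)
  arg <- max.col(t(A), ties.method = "first")
  val <- matrix(A[cbind(arg, seq_len(C))], 1)
  tapeNode(tp, val, a, function(G) {
    dA <- matrix(0, nrow(A), C)
    dA[cbind(arg, seq_len(C))] <- as.vector(G)
    list(dA)
  })
}

adGlobalMean <- function(tp, a) {
  A <- tapeVal(tp, a)
  m <- nrow(A)
  tapeNode(tp, matrix(colMeans(A), 1), a,
           function(G) list(matrix(as.vector(G), m, ncol(A), byrow = TRUE) / m))
}

adGlobalSum <- function(tp, a) {
  A <- tapeVal(tp, a)
  tapeNode(tp, matrix(colSums(A), 1), a,
           function(G) list(matrix(as.vector(G), nrow(A), ncol(A), byrow = TRUE)))
}

# sum rows by group id (1..nGroups); used for strided sparse pooling
adPoolSum <- function(tp, a, groups, nGroups) {
  A <- tapeVal(tp, a)
  rs <- rowsum(A, group = groups)
  out <- matrix(0, nGroups, ncol(A))
  out[as.integer(rownames(rs)), ] <- rs
  tapeNode(tp, out, a, function(G) list(G[groups, , drop = FALSE]))
}

adMeanPoolGroups <- function(tp, a, groups, nGroups) {
  cnt <- tabulate(groups, nbins = nGroups)
  s <- adPoolSum(tp, a, groups, nGroups)
  adRowScale(tp, s, matrix(1 / pmax(cnt, 1L)))
}

adRowScale <- function(tp, a, sConstOrId) {
  # scale each row; s may be a constant column vector or a node id
  if (is.matrix(sConstOrId)) {
    s <- as.vector(sConstOrId)
    A <- tapeVal(tp, a)
    return(tapeNode(tp, A * s, a, function(G) list(G * s)))
  }
  A <- tapeVal(tp, a); s <- as.vector(tapeVal(tp, sConstOrId))
  tapeNode(tp, A * s, c(a, sConstOrId),
           function(G) list(G * s, matrix(rowSums(G * A), ncol = 1)))
}

adTranspose <- function(tp, a) {
  tapeNode(tp, t(tapeVal(tp, a)), a, function(G) list(t(G)))
}

adShiftCols <- function(tp, a, s) {  # s = +1: y[, c] = x[, c - 1]; zero-pad
  A <- tapeVal(tp, a)
  C <- ncol(A)
  shift <- function(M, by) {
    out <- matrix(0, nrow(M), C)
    if (by > 0) out[, (1 + by):C] <- M[, 1:(C - by), drop = FALSE]
    else if (by < 0) out[, 1:(C + by)] <- M[, (1 - by):C, drop = FALSE]
    else out <- M
    out
  }
  tapeNode(tp, shift(A, s), a, function(G) list(shift(G, -s)))
}

adConcatCols <- function(tp, a, b) {
  A <- tapeVal(tp, a); B <- tapeVal(tp, b)
  ca <- ncol(A)
  tapeNode(tp, cbind(A, B), c(a, b),
           function(G) list(G[, seq_len(ca), drop = FALSE],
                            G[, -seq_len(ca), drop = FALSE]))
}

adRowNorm <- function(tp, a, eps = 1e-12) {  # L2-normalize each row
  A <- tapeVal(tp, a)
  nrm <- sqrt(rowSums(A^2)) + eps
  U <- A / nrm
  tapeNode(tp, U, a, function(G)
    list((G - U * rowSums(G * U)) / nrm))
}

adFlattenRow <- function(tp, a) {  # column-major flatten to 1 x (m*C)
  A <- tapeVal(tp, a)
  tapeNode(tp, matrix(as.vector(A), 1), a,
           function(G) list(matrix(as.vector(G), nrow(A), ncol(A))))
}

# per-segment column standardization: rows are partitioned by `groups`
# (e.g. one group per cloud in a batched forward) and each segment is
# standardized with its own statistics, so batched and single-cloud
# forwards are numerically identical
adFeatNormGroups <- function(tp, a, groups, nGroups, eps = 1e-5) {
  if (nGroups == 1L) return(adFeatNorm(tp, a, eps))
  A <- tapeVal(tp, a)
  cnt <- tabulate(groups, nbins = nGroups)
  mu <- rowsum(A, groups) / cnt
  xc <- A - mu[groups, , drop = FALSE]
  v <- rowsum(xc^2, groups) / cnt
  inv <- 1 / sqrt(v + eps)
  invE <- inv[groups, , drop = FALSE]
  Y <- xc * invE
  tapeNode(tp, Y, a, function(G) {
    gm <- (rowsum(G, groups) / cnt)[groups, , drop = FALSE]
    gym <- (rowsum(G * Y, groups) / cnt)[groups, , drop = FALSE]
    list((G - gm - Y * gym) * invE)
  })
}

# column standardization over rows (normalization computed on the forward
# sample; affine part is done with adColScale/adAddBias)
adFeatNorm <- function(tp, a, eps = 1e-5) {
  A <- tapeVal(tp, a)
  m <- nrow(A)
  if (m == 1L) return(a)
  mu <- colMeans(A)
  xc <- A - expandRow(mu, m)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  invE <- expandRow(inv, m)
  Y <- xc * invE
  tapeNode(tp, Y, a, function(G) {
    list((G - expandRow(colMeans(G), m) -
            Y * expandRow(colMeans(G * Y), m)) * invE)
  })
}

adSoftmaxRows <- function(tp, a) {
  A <- tapeVal(tp, a)
  E <- exp(A - apply(A, 1, max))
  S <- E / rowSums(E)
  tapeNode(tp, S, a, function(G) list(S * (G - rowSums(G * S))))
}

# mean cross-entropy of a B x K logit matrix against integer targets
adCrossEntropyRows <- function(tp, logits, targets) {
  L <- tapeVal(tp, logits)
  B <- nrow(L)
  Z <- L - apply(L, 1, max)
  logp <- Z - log(rowSums(exp(Z)))
  P <- exp(logp)
  cells <- cbind(seq_len(B), targets)
  tapeNode(tp, matrix(-mean(logp[cells]), 1, 1), logits, function(G) {
    D <- P
    D[cells] <- D[cells] - 1
    list(D * (as.vector(G) / B))
  })
}

# scalar cross-entropy of a 1 x K logit row against an integer target
adCrossEntropy <- function(tp, logits, target) {
  L <- tapeVal(tp, logits)
  z <- as.vector(L) - max(L)
  logp <- z - log(sum(exp(z)))
  p <- exp(logp)
  tapeNode(tp, matrix(-logp[target], 1, 1), logits, function(G) {
    d <- p
    d[target] <- d[target] - 1
    list(matrix(d * as.vector(G), 1))
  })
}

softmaxVector <- function(logits) {
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}
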