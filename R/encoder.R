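# Directed bond-level message-passing encoder (D-MPNN) in plain matrix ops.
# Messages live on directed arcs; each arc's update aggregates incoming
# messages at its source atom excluding its own reverse arc; a skip
# connection to the initial arc state is applied at every depth. Atom states
# aggregate incident arc messages together with the raw atom features, and
# the graph embedding is the mean over atoms.

relu <- function(x) (x > 0) * x

glorot <- function(nrowW, ncolW) {
  s <- sqrt(6 / (nrowW + ncolW))
  matrix(stats::runif(nrowW * ncolW, -s, s), nrowW, ncolW)
}

#' Initialize message-passing encoder parameters
#'
#' @param atomWidth,bondWidth input feature widths the encoder expects.
#' @param hidden hidden width of arc messages and atom states.
#' @param depth number of message-passing iterations (0 disables bond
#'   message passing entirely; atom states then see only atom features and
#'   the initial arc states).
#' @param seed integer seed for the random initialization.
#' @return an \code{EncoderParams} list of weight matrices
#'   (\code{Wi, bi, Wh, Wo, bo}) plus \code{depth}, \code{hidden} and the
#'   input widths.
#' @export
initEncoderParams <- function(atomWidth, bondWidth, hidden = 300L,
                              depth = 3L, seed = 0L) {
  if (depth < 0L) stopUsage("depth must be >= 0")
  withSeed(seed, {
    list(Wi = glorot(atomWidth + bondWidth, hidden),
         bi = numeric(hidden),
         Wh = glorot(hidden, hidden),
         Wo = glorot(atomWidth + hidden, hidden),
         bo = numeric(hidden),
         depth = as.integer(depth), hidden = as.integer(hidden),
         atomWidth = as.integer(atomWidth),
         bondWidth = as.integer(bondWidth))
  })
}

# Pack a list of graphs into one structure with global atom/arc indexing.
packGraphs <- function(graphs) {
  nAtoms <- vapply(graphs, numAtoms, integer(1))
  atomOffset <- cumsum(c(0L, nAtoms[-length(nAtoms)]))
  X <- do.call(rbind, lapply(graphs, atomFeatures))
  srcs <- list(); dsts <- list(); feats <- list()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    srcs[[gi]] <- g@arcSrc + atomOffset[gi]
    dsts[[gi]] <- g@arcDst + atomOffset[gi]
    feats[[gi]] <- g@arcFeat
  }
  src <- unlist(srcs); dst <- unlist(dsts)
  E <- do.call(rbind, feats)
  m <- length(src)
  list(X = X, src = src, dst = dst, E = E,
       rev = if (m > 0) reverseArcIndex(m) else integer(0),
       graphId = rep(seq_along(graphs), nAtoms),
       nGraphs = length(graphs),
       nAtomsPerGraph = nAtoms)
}

# Sum rows of `x` grouped by integer index `idx` into `n` output rows
# (rows with no contributions are zero).
scatterSum <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  if (length(idx) == 0L) return(out)
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Forward pass over a packed graph set; returns per-graph embeddings and,
# optionally, the cache needed for the backward pass.
encoderForward <- function(pack, params, keepCache = FALSE) {
  nA <- nrow(pack$X)
  m <- length(pack$src)
  if (ncol(pack$X) != params$atomWidth ||
      (m > 0 && ncol(pack$E) != params$bondWidth))
    stopShape("graph feature widths (", ncol(pack$X), ",",
              if (m > 0) ncol(pack$E) else NA, ") do not match encoder (",
              params$atomWidth, ",", params$bondWidth, ")")
  h <- params$hidden
  Ms <- vector("list", params$depth)
  Hs <- vector("list", params$depth)
  if (m > 0 && params$depth > 0L) {
    Hin <- cbind(pack$X[pack$src, , drop = FALSE], pack$E)
    H0 <- relu(sweep(Hin %*% params$Wi, 2, params$bi, "+"))
    H <- H0
    for (t in seq_len(params$depth)) {
      Ain <- scatterSum(H, pack$dst, nA)
      M <- Ain[pack$src, , drop = FALSE] - H[pack$rev, , drop = FALSE]
      H <- relu(H0 + M %*% params$Wh)
      if (keepCache) { Ms[[t]] <- M; Hs[[t]] <- H }
    }
    Aatom <- scatterSum(H, pack$dst, nA)
  } else {
    # depth 0 disables bond-level message passing: atom states see only the
    # raw atom features, so the embedding is independent of bond features
    Hin <- NULL; H0 <- NULL; H <- NULL
    Aatom <- matrix(0, nA, h)
  }
  Qin <- cbind(pack$X, Aatom)
  Q <- relu(sweep(Qin %*% params$Wo, 2, params$bo, "+"))
  emb <- scatterSum(Q, pack$graphId, pack$nGraphs) / pack$nAtomsPerGraph
  out <- list(emb = emb)
  if (keepCache)
    out$cache <- list(Hin = Hin, H0 = H0, Ms = Ms, Hs = Hs, Qin = Qin, Q = Q)
  out
}

# Backward pass: gradient of the loss w.r.t. encoder parameters given the
# gradient w.r.t. the per-graph embeddings.
encoderBackward <- function(pack, params, cache, dEmb) {
  nA <- nrow(pack$X)
  m <- length(pack$src)
  dQ <- (dEmb / pack$nAtomsPerGraph)[pack$graphId, , drop = FALSE]
  dZq <- dQ * (cache$Q > 0)
  dWo <- crossprod(cache$Qin, dZq)
  dbo <- colSums(dZq)
  grads <- list(Wi = matrix(0, nrow(params$Wi), ncol(params$Wi)),
                bi = numeric(params$hidden),
                Wh = matrix(0, params$hidden, params$hidden),
                Wo = dWo, bo = dbo)
  if (m == 0L || params$depth == 0L) return(grads)

  dAatom <- dZq %*% t(params$Wo[params$atomWidth + seq_len(params$hidden), ,
                                drop = FALSE])
  dH <- dAatom[pack$dst, , drop = FALSE]
  dH0 <- matrix(0, m, params$hidden)
  dWh <- matrix(0, params$hidden, params$hidden)
  for (t in rev(seq_len(params$depth))) {
    Ht <- cache$Hs[[t]]
    dZ <- dH * (Ht > 0)
    dWh <- dWh + crossprod(cache$Ms[[t]], dZ)
    dH0 <- dH0 + dZ
    dM <- dZ %*% t(params$Wh)
    dAin <- scatterSum(dM, pack$src, nA)
    dH <- dAin[pack$dst, , drop = FALSE] - dM[pack$rev, , drop = FALSE]
  }
  dH0 <- dH0 + dH
  dZ0 <- dH0 * (cache$H0 > 0)
  grads$Wi <- crossprod(cache$Hin, dZ0)
  grads$bi <- colSums(dZ0)
  grads$Wh <- dWh
  grads
}

#' Encode a single graph into its embedding vector
#'
#' @param graph a [MolGraph-class] or [CGRGraph-class].
#' @param params an [initEncoderParams()] parameter set matching the graph's
#'   feature widths.
#' @return a numeric embedding of length \code{params$hidden}.
#' @export
encodeGraph <- function(graph, params) {
  pack <- packGraphs(list(graph))
  drop(encoderForward(pack, params)$emb)
}

# ---- feed-forward head -----------------------------------------------------

initHeadParams <- function(inputWidth, hidden = 300L, layers = 2L,
                           outputs = 2L, seed = 0L) {
  withSeed(seed, {
    dims <- c(inputWidth, rep(hidden, layers), outputs)
    W <- list(); b <- list()
    for (l in seq_len(length(dims) - 1L)) {
      W[[l]] <- glorot(dims[l], dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
    }
    list(W = W, b = b, layers = as.integer(layers),
         inputWidth = as.integer(inputWidth), outputs = as.integer(outputs))
  })
}

# Forward through the head. dropMasks, when given, is a list of 0/1 matrices
# applied to each hidden activation (training-time dropout, pre-scaled).
headForward <- function(X, head, dropMasks = NULL, keepCache = FALSE) {
  nL <- length(head$W)
  As <- vector("list", nL)
  A <- X
  for (l in seq_len(nL)) {
    Z <- sweep(A %*% head$W[[l]], 2, head$b[[l]], "+")
    if (l < nL) {
      Z <- relu(Z)
      if (!is.null(dropMasks)) Z <- Z * dropMasks[[l]]
    }
    As[[l]] <- A
    A <- Z
  }
  out <- list(Y = A)
  if (keepCache) out$cache <- list(As = As, dropMasks = dropMasks)
  out
}

headBackward <- function(X, head, cache, dY) {
  nL <- length(head$W)
  dW <- vector("list", nL); db <- vector("list", nL)
  dA <- dY   # gradient w.r.t. the (pre-activation) output of layer l
  for (l in rev(seq_len(nL))) {
    A <- cache$As[[l]]   # input of layer l = masked activation of layer l-1
    dW[[l]] <- crossprod(A, dA)
    db[[l]] <- colSums(dA)
    dA <- dA %*% t(head$W[[l]])
    if (l > 1L) {
      # through ReLU (+ dropout scale) of hidden layer l-1: the stored input
      # A is relu(Z) * mask, so dZ = dA * mask * (Z > 0); (A > 0) selects
      # the surviving positive units and the mask supplies the scale.
      dA <- dA * (A > 0)
      if (!is.null(cache$dropMasks)) dA <- dA * cache$dropMasks[[l - 1L]]
    }
  }
  list(dW = dW, db = db, dX = dA)
}
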