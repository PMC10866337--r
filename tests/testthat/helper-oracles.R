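# Independent dense oracle: the same message-passing contract implemented
# with explicit arc-by-arc loops (no scatter/batching), used to validate the
# vectorized implementation.
denseEncodeOracle <- function(graph, params) {
  X <- atomFeatures(graph)
  nA <- nrow(X)
  src <- graph@arcSrc; dst <- graph@arcDst
  m <- length(src)
  relu0 <- function(v) pmax(v, 0)
  if (m > 0 && params$depth > 0) {
    H <- matrix(0, m, params$hidden)
    H0 <- matrix(0, m, params$hidden)
    for (k in seq_len(m)) {
      feat <- c(X[src[k], ], graph@arcFeat[k, ])
      H0[k, ] <- relu0(drop(feat %*% params$Wi) + params$bi)
    }
    H <- H0
    for (t in seq_len(params$depth)) {
      Hnew <- matrix(0, m, params$hidden)
      for (k in seq_len(m)) {
        msg <- numeric(params$hidden)
        for (k2 in seq_len(m)) {
          # arcs arriving at this arc's source, excluding the reverse arc
          if (dst[k2] == src[k] && !(src[k2] == dst[k] && dst[k2] == src[k]))
            msg <- msg + H[k2, ]
        }
        Hnew[k, ] <- relu0(H0[k, ] + drop(msg %*% params$Wh))
      }
      H <- Hnew
    }
    Q <- matrix(0, nA, params$hidden)
    for (a in seq_len(nA)) {
      agg <- numeric(params$hidden)
      for (k in seq_len(m)) if (dst[k] == a) agg <- agg + H[k, ]
      Q[a, ] <- relu0(drop(c(X[a, ], agg) %*% params$Wo) + params$bo)
    }
  } else {
    Q <- matrix(0, nA, params$hidden)
    for (a in seq_len(nA))
      Q[a, ] <- relu0(drop(c(X[a, ], numeric(params$hidden)) %*% params$Wo) +
                      params$bo)
  }
  colMeans(Q)
}
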