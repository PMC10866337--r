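#' Feature schema for atom and bond featurization
#'
#' Defines the deterministic atom and bond feature vocabularies used by the
#' graph encoders. Atom block: element one-hot over \{H, C, N, O, S, other\},
#' degree 0--5 one-hot, formal charge -2..+2 one-hot, hybridization one-hot
#' \{sp, sp2, sp3, other\}, aromatic flag, total hydrogen count 0--4 one-hot,
#' and atomic mass scaled by 1/100. Bond block: bond-order one-hot
#' \{single, double, triple, aromatic\}, conjugated flag, in-ring flag, and a
#' null-bond flag (set only for the absent side of a CGR bond).
#'
#' An optional additional atom block (off by default) appends six descriptors:
#' radical-electron count, smallest-ring size, lone-pair count, H-bond donor
#' and acceptor flags, and Pauling electronegativity scaled by 1/4.
#'
#' @param extraAtomFeatures logical; append the additional atom block.
#' @return a \code{FeatureSchema} list with element \code{atomWidth},
#'   \code{bondWidth}, \code{extraAtomFeatures} and \code{version}.
#' @export
featureSchema <- function(extraAtomFeatures = FALSE) {
  atomWidth <- 6L + 6L + 5L + 4L + 1L + 5L + 1L + if (extraAtomFeatures) 6L else 0L
  structure(list(atomWidth = atomWidth, bondWidth = 7L,
                 extraAtomFeatures = extraAtomFeatures, version = "1"),
            class = "FeatureSchema")
}

oneHot <- function(value, levels) {
  v <- numeric(length(levels))
  idx <- match(value, levels)
  if (is.na(idx)) idx <- length(levels)   # "other" fallback = last slot
  v[idx] <- 1
  v
}

hybridization <- function(mol, a) {
  if (mol$atoms$aromatic[a]) return("sp2")
  b <- mol$bonds
  orders <- c(b$order[b$i == a], b$order[b$j == a])
  if (any(orders == 3) || sum(orders == 2) >= 2) "sp"
  else if (any(orders == 2)) "sp2"
  else "sp3"
}

smallestRingSize <- function(mol, a) {
  b <- mol$bonds[mol$bonds$inRing, , drop = FALSE]
  if (nrow(b) == 0L) return(0L)
  touching <- b$i == a | b$j == a
  if (!any(touching)) return(0L)
  # BFS over ring bonds only; shortest cycle through `a`
  nA <- nrow(mol$atoms)
  adj <- vector("list", nA)
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  best <- 0L
  starts <- unique(c(b$j[b$i == a], b$i[b$j == a]))
  for (s in starts) {
    dist <- rep(NA_integer_, nA); dist[a] <- 0L
    queue <- a
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (u == a && v == s) next   # skip the direct edge a-s
        if (is.na(dist[v])) { dist[v] <- dist[u] + 1L; queue <- c(queue, v) }
      }
    }
    if (!is.na(dist[s])) {
      len <- dist[s] + 1L
      if (best == 0L || len < best) best <- len
    }
  }
  best
}

.VALENCE_ELECTRONS <- c(H = 1, B = 3, C = 4, N = 5, O = 6, P = 5, S = 6,
                        F = 7, Cl = 7, Br = 7, I = 7)

atomFeatureMatrix <- function(mol, schema) {
  nA <- nrow(mol$atoms)
  conj <- bondConjugation(mol)
  rows <- lapply(seq_len(nA), function(a) {
    at <- mol$atoms[a, ]
    base <- c(
      oneHot(at$element, c("H", "C", "N", "O", "S", "other")),
      oneHot(min(at$degree, 5L), 0:5),
      oneHot(max(-2L, min(2L, at$charge)), -2:2),
      oneHot(hybridization(mol, a), c("sp", "sp2", "sp3", "other")),
      as.numeric(at$aromatic),
      oneHot(min(at$totalH, 4L), 0:4),
      .ATOMIC_MASS[[at$element]] / 100
    )
    if (schema$extraAtomFeatures) {
      ve <- .VALENCE_ELECTRONS[[at$element]]
      bsum <- bondOrderSum(mol, a)
      lp <- max(0, floor((ve - at$charge - bsum - at$totalH - at$radicals) / 2))
      base <- c(base,
                at$radicals,
                smallestRingSize(mol, a),
                lp,
                as.numeric(at$element %in% c("N", "O") && at$totalH > 0),
                as.numeric(at$element %in% c("N", "O")),
                .ELECTRONEGATIVITY[[at$element]] / 4)
    }
    base
  })
  do.call(rbind, rows)
}

bondOrderSum <- function(mol, a) {
  b <- mol$bonds
  sum(c(b$order[b$i == a], b$order[b$j == a]))
}

# A bond is conjugated if aromatic, or if it is a multiple bond adjacent to
# another multiple/aromatic bond, or a single bond bridging two multiple or
# aromatic bonds.
bondConjugation <- function(mol) {
  b <- mol$bonds
  nB <- nrow(b)
  if (nB == 0L) return(logical(0))
  hasMultiple <- vapply(seq_len(nrow(mol$atoms)), function(a) {
    any(c(b$order[b$i == a], b$order[b$j == a]) > 1)
  }, logical(1))
  out <- logical(nB)
  for (k in seq_len(nB)) {
    if (b$aromatic[k]) { out[k] <- TRUE; next }
    i <- b$i[k]; j <- b$j[k]
    otherMult <- function(a) {
      ks <- which((b$i == a | b$j == a) & seq_len(nB) != k)
      any(b$order[ks] > 1)
    }
    if (b$order[k] > 1) out[k] <- otherMult(i) || otherMult(j)
    else out[k] <- otherMult(i) && otherMult(j)
  }
  out
}

bondFeatureVector <- function(order, aromatic, inRing, conjugated,
                              null = FALSE) {
  if (null) return(c(0, 0, 0, 0, 0, 0, 1))
  ord <- if (aromatic || order == 1.5) "aromatic" else as.character(order)
  c(oneHot(ord, c("1", "2", "3", "aromatic")),
    as.numeric(conjugated), as.numeric(inRing), 0)
}

#' MolGraph: a featurized molecular graph
#'
#' Atoms as feature vectors and bonds as symmetric directed arc pairs, ready
#' for the message-passing encoder. Arc \code{2k-1} and arc \code{2k} are the
#' two directions of undirected bond \code{k} and share its feature vector.
#'
#' @slot atoms numeric matrix, one row per atom.
#' @slot arcSrc,arcDst integer vectors of arc endpoints.
#' @slot arcFeat numeric matrix, one row per directed arc.
#' @slot componentCount number of connected components.
#' @export
setClass("MolGraph",
         representation(atoms = "matrix", arcSrc = "integer",
                        arcDst = "integer", arcFeat = "matrix",
                        componentCount = "integer"))

setValidity("MolGraph", function(object) {
  m <- length(object@arcSrc)
  if (length(object@arcDst) != m) return("arcSrc/arcDst length mismatch")
  if (nrow(object@arcFeat) != m && m > 0) return("arcFeat row mismatch")
  if (m %% 2L != 0L) return("arcs must come in reverse pairs")
  if (m > 0) {
    rev <- reverseArcIndex(m)
    if (!all(object@arcSrc == object@arcDst[rev]))
      return("arc list not symmetric")
  }
  TRUE
})

setMethod("show", "MolGraph", function(object) {
  cat(class(object), ": ", nrow(object@atoms), " atoms (width ",
      ncol(object@atoms), "), ", length(object@arcSrc) / 2,
      " bonds, ", object@componentCount, " component(s)\n", sep = "")
})

#' @describeIn MolGraph number of atoms
#' @param g a \code{MolGraph}.
#' @export
numAtoms <- function(g) nrow(g@atoms)

#' @describeIn MolGraph atom feature matrix
#' @export
atomFeatures <- function(g) g@atoms

#' @describeIn MolGraph arc feature matrix (both directions per bond)
#' @export
arcFeatures <- function(g) g@arcFeat

#' CGRGraph: condensed graph of reaction
#'
#' A [MolGraph-class] whose nodes are the mapped atoms (indexed by atom-map
#' number) and whose feature vectors are reactant features concatenated with
#' the product-minus-reactant difference; bonds are the union of both sides'
#' bonds, with the missing side contributing a null-bond block.
#' @export
setClass("CGRGraph", contains = "MolGraph")

reverseArcIndex <- function(m) {
  idx <- seq_len(m)
  idx + ifelse(idx %% 2L == 1L, 1L, -1L)
}

makeArcs <- function(bi, bj, bondFeat) {
  nB <- length(bi)
  if (nB == 0L)
    return(list(src = integer(0), dst = integer(0),
                feat = matrix(numeric(0), 0, ncol(bondFeat))))
  src <- integer(2L * nB); dst <- integer(2L * nB)
  src[seq(1, 2 * nB, 2)] <- bi; dst[seq(1, 2 * nB, 2)] <- bj
  src[seq(2, 2 * nB, 2)] <- bj; dst[seq(2, 2 * nB, 2)] <- bi
  feat <- bondFeat[rep(seq_len(nB), each = 2), , drop = FALSE]
  list(src = src, dst = dst, feat = feat)
}

#' Build a featurized molecular graph from a SMILES
#'
#' @param smiles a SMILES string (or an already parsed internal molecule).
#' @param schema a [featureSchema()].
#' @return a [MolGraph-class].
#' @examples
#' g <- buildMolGraph("CCO")
#' numAtoms(g)
#' @export
buildMolGraph <- function(smiles, schema = featureSchema()) {
  mol <- if (is.character(smiles)) parseSmiles(smiles) else smiles
  X <- atomFeatureMatrix(mol, schema)
  conj <- bondConjugation(mol)
  nB <- nrow(mol$bonds)
  bf <- if (nB > 0) {
    do.call(rbind, lapply(seq_len(nB), function(k) {
      bondFeatureVector(mol$bonds$order[k], mol$bonds$aromatic[k],
                        mol$bonds$inRing[k], conj[k])
    }))
  } else matrix(numeric(0), 0, schema$bondWidth)
  arcs <- makeArcs(mol$bonds$i, mol$bonds$j, bf)
  new("MolGraph", atoms = X, arcSrc = arcs$src, arcDst = arcs$dst,
      arcFeat = arcs$feat, componentCount = as.integer(mol$component_count))
}

sideFeaturesByMap <- function(mol, schema, maps) {
  X <- atomFeatureMatrix(mol, schema)
  X[match(maps, mol$atoms$map), , drop = FALSE]
}

sideBondFeatureMap <- function(mol, schema) {
  conj <- bondConjugation(mol)
  out <- list()
  b <- mol$bonds
  if (nrow(b) == 0L) return(out)
  for (k in seq_len(nrow(b))) {
    m1 <- mol$atoms$map[b$i[k]]; m2 <- mol$atoms$map[b$j[k]]
    key <- paste(min(m1, m2), max(m1, m2), sep = "_")
    out[[key]] <- bondFeatureVector(b$order[k], b$aromatic[k], b$inRing[k],
                                    conj[k])
  }
  out
}

#' Build the condensed graph of reaction (CGR)
#'
#' Superposes the reactant and product graphs over the atom-map bijection.
#' Each node's vector is \code{[reactant features, product - reactant]};
#' each bond present on either side gets
#' \code{[reactant bond features, product - reactant]}, where an absent side
#' contributes a null-bond vector (zeros with the null flag set). For an
#' identity reaction all difference blocks are exactly zero.
#'
#' @param r a [MappedReaction-class].
#' @param schema a [featureSchema()].
#' @return a [CGRGraph-class]; nodes are ordered by atom-map number.
#' @export
buildCGR <- function(r, schema = featureSchema()) {
  maps <- sort(r@mapPairs[, "map"])
  Xr <- sideFeaturesByMap(r@reactant, schema, maps)
  Xp <- sideFeaturesByMap(r@product, schema, maps)
  X <- cbind(Xr, Xp - Xr)

  rb <- sideBondFeatureMap(r@reactant, schema)
  pb <- sideBondFeatureMap(r@product, schema)
  nullVec <- bondFeatureVector(0, FALSE, FALSE, FALSE, null = TRUE)
  keys <- union(names(rb), names(pb))
  nB <- length(keys)
  mapIndex <- match(maps, maps)   # identity; node index = rank of map number
  names(mapIndex) <- maps
  bi <- integer(nB); bj <- integer(nB)
  bf <- matrix(0, nB, 2L * schema$bondWidth)
  for (k in seq_along(keys)) {
    ms <- as.integer(strsplit(keys[k], "_")[[1]])
    bi[k] <- match(ms[1], maps); bj[k] <- match(ms[2], maps)
    fr <- if (!is.null(rb[[keys[k]]])) rb[[keys[k]]] else nullVec
    fp <- if (!is.null(pb[[keys[k]]])) pb[[keys[k]]] else nullVec
    bf[k, ] <- c(fr, fp - fr)
  }
  arcs <- makeArcs(bi, bj, bf)
  new("CGRGraph", atoms = X, arcSrc = arcs$src, arcDst = arcs$dst,
      arcFeat = arcs$feat,
      componentCount = as.integer(r@reactant$component_count))
}

#' Append user-supplied atom/bond features to a graph
#'
#' Additional atom features are appended to every atom row (for a
#' [CGRGraph-class], rows are indexed by atom-map number, so extras must be
#' supplied in map order). Additional bond features are appended to both
#' directed arcs of each bond. Molecular-level extras are not part of the
#' graph; they are concatenated with the embeddings at the regression head
#' (see \code{extras} columns in the pair table).
#'
#' @param graph a [MolGraph-class] or [CGRGraph-class].
#' @param atomExtras numeric matrix with one row per atom, or NULL.
#' @param bondExtras numeric matrix with one row per undirected bond (in the
#'   graph's bond order), or NULL.
#' @return the augmented graph.
#' @export
injectExtraFeatures <- function(graph, atomExtras = NULL, bondExtras = NULL) {
  if (!is.null(atomExtras)) {
    atomExtras <- as.matrix(atomExtras)
    if (nrow(atomExtras) != nrow(graph@atoms))
      stopFeature("atom extras have ", nrow(atomExtras),
                  " rows but graph has ", nrow(graph@atoms), " atoms")
    if (any(!is.finite(atomExtras))) stopFeature("non-finite atom extras")
    graph@atoms <- cbind(graph@atoms, atomExtras)
  }
  if (!is.null(bondExtras)) {
    bondExtras <- as.matrix(bondExtras)
    nB <- length(graph@arcSrc) / 2L
    if (nrow(bondExtras) != nB)
      stopFeature("bond extras have ", nrow(bondExtras),
                  " rows but graph has ", nB, " bonds")
    graph@arcFeat <- cbind(graph@arcFeat,
                           bondExtras[rep(seq_len(nB), each = 2), ,
                                      drop = FALSE])
  }
  graph
}
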