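# Synthetic fixture generator: templated, atom-mapped toy radical reactions
# (H-abstraction, H-migration, radical addition over small H/C/O fragments,
# <= 10 heavy atoms), a solvent library with polarity descriptors, and a
# transparent closed-form surrogate target, so the full pipeline is testable
# without any external data.

# ---- internal molecule builder and mapped-SMILES writer -------------------
# A fragment is list(el = elements, nH = written hydrogen counts,
# bonds = list of c(i, j, order)). Node index = atom-map number after
# assembly; written H counts are constant across a reaction so radicals are
# implied by valence and reactions stay balanced by construction.

mkFrag <- function(el, nH, bonds = list()) list(el = el, nH = nH, bonds = bonds)

mergeFrags <- function(...) {
  frags <- list(...)
  el <- character(0); nH <- integer(0); bonds <- list()
  offsets <- integer(length(frags))
  for (i in seq_along(frags)) {
    offsets[i] <- length(el)
    f <- frags[[i]]
    el <- c(el, f$el); nH <- c(nH, f$nH)
    bonds <- c(bonds, lapply(f$bonds, function(b) b + c(offsets[i], offsets[i], 0)))
  }
  list(el = el, nH = nH, bonds = bonds, offsets = offsets)
}

componentsOf <- function(n, bonds) {
  id <- seq_len(n)
  repeat {
    changed <- FALSE
    for (b in bonds) {
      m <- min(id[b[1]], id[b[2]])
      if (id[b[1]] != m || id[b[2]] != m) {
        id[id == id[b[1]]] <- m; id[id == id[b[2]]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  id
}

writeMappedSide <- function(el, nH, bonds) {
  n <- length(el)
  adj <- vector("list", n)
  for (b in bonds) {
    adj[[b[1]]] <- rbind(adj[[b[1]]], c(b[2], b[3]))
    adj[[b[2]]] <- rbind(adj[[b[2]]], c(b[1], b[3]))
  }
  token <- function(a) {
    if (el[a] == "H") return(paste0("[H:", a, "]"))
    hs <- if (nH[a] == 0L) "" else if (nH[a] == 1L) "H" else paste0("H", nH[a])
    paste0("[", el[a], hs, ":", a, "]")
  }
  bondSym <- function(o) switch(as.character(o), "1" = "", "2" = "=", "3" = "#")
  visited <- logical(n)
  render <- function(a, parent) {
    visited[a] <<- TRUE
    out <- token(a)
    nbrs <- adj[[a]]
    if (!is.null(nbrs)) {
      kids <- nbrs[nbrs[, 1] != parent & !visited[nbrs[, 1]], , drop = FALSE]
      if (nrow(kids) > 0) {
        for (k in seq_len(nrow(kids))) {
          if (visited[kids[k, 1]]) next
          sub <- paste0(bondSym(kids[k, 2]), render(kids[k, 1], a))
          out <- if (k < nrow(kids)) paste0(out, "(", sub, ")")
                 else paste0(out, sub)
        }
      }
    }
    out
  }
  comp <- componentsOf(n, bonds)
  parts <- vapply(unique(comp), function(cc) {
    render(which(comp == cc)[1], 0L)
  }, character(1))
  paste(parts, collapse = ".")
}

reactionText <- function(nodes, bondsR, bondsP) {
  paste0(writeMappedSide(nodes$el, nodes$nH, bondsR), ">>",
         writeMappedSide(nodes$el, nodes$nH, bondsP))
}

# ---- fragment library -----------------------------------------------------

radicalFrags <- function() list(
  methyl = mkFrag("C", 3L),
  ethyl = mkFrag(c("C", "C"), c(2L, 3L), list(c(1, 2, 1))),
  isopropyl = mkFrag(c("C", "C", "C"), c(1L, 3L, 3L),
                     list(c(1, 2, 1), c(1, 3, 1))),
  npropyl = mkFrag(c("C", "C", "C"), c(2L, 2L, 3L),
                   list(c(1, 2, 1), c(2, 3, 1))),
  tbutyl = mkFrag(c("C", "C", "C", "C"), c(0L, 3L, 3L, 3L),
                  list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1))),
  hydroxyl = mkFrag("O", 1L),
  methoxy = mkFrag(c("O", "C"), c(0L, 3L), list(c(1, 2, 1))),
  ethoxy = mkFrag(c("O", "C", "C"), c(0L, 2L, 3L),
                  list(c(1, 2, 1), c(2, 3, 1))),
  hydroperoxyl = mkFrag(c("O", "O"), c(0L, 1L), list(c(1, 2, 1)))
)

# substrates: donor site is atom 1 with one abstractable H made explicit
substrateFrags <- function() list(
  methane = mkFrag("C", 3L),
  ethane = mkFrag(c("C", "C"), c(2L, 3L), list(c(1, 2, 1))),
  propane2 = mkFrag(c("C", "C", "C"), c(1L, 3L, 3L),
                    list(c(1, 2, 1), c(1, 3, 1))),
  isobutane = mkFrag(c("C", "C", "C", "C"), c(0L, 3L, 3L, 3L),
                     list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1))),
  methanolO = mkFrag(c("O", "C"), c(0L, 3L), list(c(1, 2, 1))),
  methanolC = mkFrag(c("C", "O"), c(2L, 1L), list(c(1, 2, 1))),
  ethanolO = mkFrag(c("O", "C", "C"), c(0L, 2L, 3L),
                    list(c(1, 2, 1), c(2, 3, 1))),
  ethanolC = mkFrag(c("C", "C", "O"), c(1L, 3L, 1L),
                    list(c(1, 2, 1), c(1, 3, 1))),
  propane1 = mkFrag(c("C", "C", "C"), c(2L, 2L, 3L),
                    list(c(1, 2, 1), c(2, 3, 1))),
  butane1 = mkFrag(c("C", "C", "C", "C"), c(2L, 2L, 2L, 3L),
                   list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))),
  butane2 = mkFrag(c("C", "C", "C", "C"), c(1L, 3L, 2L, 3L),
                   list(c(1, 2, 1), c(1, 3, 1), c(3, 4, 1))),
  propanolO = mkFrag(c("O", "C", "C", "C"), c(0L, 2L, 2L, 3L),
                     list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))),
  isopropanolO = mkFrag(c("O", "C", "C", "C"), c(0L, 1L, 3L, 3L),
                        list(c(1, 2, 1), c(2, 3, 1), c(2, 4, 1))),
  dimethylether = mkFrag(c("C", "O", "C"), c(2L, 0L, 3L),
                         list(c(1, 2, 1), c(2, 3, 1)))
)

alkeneFrags <- function() list(
  ethene = mkFrag(c("C", "C"), c(2L, 2L), list(c(1, 2, 2))),
  propene = mkFrag(c("C", "C", "C"), c(2L, 1L, 3L),
                   list(c(1, 2, 2), c(2, 3, 1))),
  isobutene = mkFrag(c("C", "C", "C", "C"), c(2L, 0L, 3L, 3L),
                     list(c(1, 2, 2), c(2, 3, 1), c(2, 4, 1))),
  butene2 = mkFrag(c("C", "C", "C", "C"), c(3L, 1L, 1L, 3L),
                   list(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1))),
  butene1 = mkFrag(c("C", "C", "C", "C"), c(2L, 1L, 2L, 3L),
                   list(c(1, 2, 2), c(2, 3, 1), c(3, 4, 1))),
  methylvinylether = mkFrag(c("C", "C", "O", "C"), c(2L, 1L, 0L, 3L),
                            list(c(1, 2, 2), c(2, 3, 1), c(3, 4, 1)))
)

# chains for 1,n-H migration: radical acceptor at atom 1, H donor at the
# last heavy atom
migrationFrags <- function() list(
  shift12_CCO = mkFrag(c("C", "C", "O"), c(2L, 2L, 0L),
                       list(c(1, 2, 1), c(2, 3, 1))),
  shift13_CCCO = mkFrag(c("C", "C", "C", "O"), c(2L, 2L, 2L, 0L),
                        list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))),
  shift12_CC = mkFrag(c("C", "C"), c(2L, 2L), list(c(1, 2, 1))),
  shift13_CCC = mkFrag(c("C", "C", "C"), c(2L, 2L, 2L),
                       list(c(1, 2, 1), c(2, 3, 1))),
  shift12_OC = mkFrag(c("O", "C"), c(0L, 2L), list(c(1, 2, 1))),
  shift13_OCC = mkFrag(c("O", "C", "C"), c(0L, 2L, 2L),
                       list(c(1, 2, 1), c(2, 3, 1))),
  shift14_CCCC = mkFrag(c("C", "C", "C", "C"), c(2L, 2L, 2L, 2L),
                        list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))),
  shift14_CCCO = mkFrag(c("C", "C", "C", "O"), c(2L, 2L, 2L, 0L),
                        list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))),
  shift14_OCCC = mkFrag(c("O", "C", "C", "C"), c(0L, 2L, 2L, 2L),
                        list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))),
  shift15_CCCCO = mkFrag(c("C", "C", "C", "C", "O"), c(2L, 2L, 2L, 2L, 0L),
                         list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 5, 1)))
)

buildAbstraction <- function(substrate, radical) {
  # nodes: substrate, explicit H, radical
  m <- mergeFrags(substrate, mkFrag("H", 0L), radical)
  hIdx <- m$offsets[2] + 1L
  radSite <- m$offsets[3] + 1L
  bondsR <- c(m$bonds, list(c(1L, hIdx, 1L)))
  bondsP <- c(m$bonds, list(c(radSite, hIdx, 1L)))
  list(nodes = m, bondsR = bondsR, bondsP = bondsP, family = "H-abstraction")
}

buildMigration <- function(chain) {
  m <- mergeFrags(chain, mkFrag("H", 0L))
  hIdx <- m$offsets[2] + 1L
  donor <- length(chain$el)
  bondsR <- c(m$bonds, list(c(donor, hIdx, 1L)))
  bondsP <- c(m$bonds, list(c(1L, hIdx, 1L)))
  list(nodes = m, bondsR = bondsR, bondsP = bondsP, family = "H-migration")
}

buildAddition <- function(alkene, radical) {
  m <- mergeFrags(alkene, radical)
  radSite <- m$offsets[2] + 1L
  piBond <- which(vapply(m$bonds, function(b) b[3] == 2L, logical(1)))[1]
  bondsP <- m$bonds
  bondsP[[piBond]][3] <- 1L
  bondsP <- c(bondsP, list(c(2L, radSite, 1L)))  # add at the second sp2 C
  list(nodes = m, bondsR = m$bonds, bondsP = bondsP, family = "R-addition")
}

#' Enumerate the templated toy reaction pool
#'
#' All combinations of the fragment library under the three templates
#' (bimolecular H-abstraction, unimolecular 1,n-H migration, radical
#' addition to a double bond), de-duplicated by [reactionKey()].
#'
#' @return a data.frame with columns \code{rxn_smiles} (forward, atom
#'   mapped), \code{family} and \code{reaction_key}.
#' @export
reactionPool <- function() {
  out <- list()
  for (s in substrateFrags()) for (r in radicalFrags())
    out[[length(out) + 1L]] <- buildAbstraction(s, r)
  for (chain in migrationFrags())
    out[[length(out) + 1L]] <- buildMigration(chain)
  for (a in alkeneFrags()) for (r in radicalFrags())
    out[[length(out) + 1L]] <- buildAddition(a, r)
  txt <- vapply(out, function(x) reactionText(x$nodes, x$bondsR, x$bondsP),
                character(1))
  fam <- vapply(out, `[[`, character(1), "family")
  keys <- vapply(txt, function(s) reactionKey(parseMappedReaction(s)),
                 character(1))
  keep <- !duplicated(keys)
  data.frame(rxn_smiles = txt[keep], family = fam[keep],
             reaction_key = unname(keys[keep]), stringsAsFactors = FALSE)
}

#' Generate atom-mapped toy radical reactions
#'
#' Samples \code{n} distinct undirected reactions from [reactionPool()] and
#' emits both directions of each, so the result has \code{2n} directed
#' [MappedReaction-class] objects (forward instances first). Names carry the
#' generating template family.
#'
#' @param n number of undirected reactions (pool currently holds ~80).
#' @param seed integer seed.
#' @return a named list of \code{2n} [MappedReaction-class] objects.
#' @export
generateReactions <- function(n, seed = 0L) {
  pool <- reactionPool()
  if (n < 1L) stopUsage("n must be >= 1")
  if (n > nrow(pool))
    stopUsage("n exceeds the reaction pool size (", nrow(pool), ")")
  pick <- withSeed(deriveSeed(seed, 401L), sample(nrow(pool), n))
  fwd <- lapply(pool$rxn_smiles[pick], parseMappedReaction)
  rev <- lapply(fwd, reverseReaction)
  out <- c(fwd, rev)
  names(out) <- c(pool$family[pick], pool$family[pick])
  out
}

# ---- solvent library ------------------------------------------------------

solventPool <- function() {
  alkyl <- c("C", "CC", "CCC", "CCCC", "CC(C)C")
  alkanes <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC",
               "CC(C)C", "CC(C)CC", "CC(C)(C)C", "CC(C)CCC", "CCC(C)CC")
  alcohols <- paste0(c("C", "CC", "CCC", "CCCC", "CCCCC", "CC(C)C",
                       "CC(C)CC", "CC(C)(C)C"), "O")
  diols <- c("OCCO", "OCCCO", "OCC(O)C")
  ethers <- c(unlist(lapply(seq_along(alkyl), function(i)
    vapply(seq(i, length(alkyl)), function(j)
      paste0(alkyl[i], "O", alkyl[j]), character(1)))))
  nitriles <- paste0(c("C", "CC", "CCC", "CC(C)C", "CCCC"), "C#N")
  amides <- c("NC=O", "CNC=O", "CN(C)C=O", "CC(=O)N", "CC(=O)NC",
              "CC(=O)N(C)C", "CCC(=O)N")
  unique(c("O", alkanes, alcohols, diols, ethers, nitriles, amides))
}

#' Generate a solvent library with polarity descriptors
#'
#' Draws \code{n} distinct solvents from a fixed templated pool (water,
#' alkanes, alcohols, diols, ethers, nitriles, amides; H/C/N/O only) and
#' annotates each with the deterministic polarity proxy
#' (heteroatom count / heavy-atom count, 1.0 for water, 0.0 for alkanes)
#' and the H-bond-donor count (hydrogens on N or O).
#'
#' @param n number of solvents (at least 2, at most the pool size).
#' @param seed integer seed.
#' @return data.frame with columns \code{smiles}, \code{polarity},
#'   \code{hbd}.
#' @export
generateSolventLibrary <- function(n, seed = 0L) {
  pool <- solventPool()
  if (n < 2L) stopUsage("n must be >= 2")
  if (n > length(pool))
    stopUsage("n exceeds the solvent pool size (", length(pool), ")")
  pick <- withSeed(deriveSeed(seed, 402L), sample(length(pool), n))
  smiles <- pool[pick]
  desc <- t(vapply(smiles, function(s) {
    mol <- parseSmiles(s)
    heavy <- mol$atoms$element != "H"
    hetero <- heavy & !mol$atoms$element %in% c("C", "H")
    hbd <- sum(mol$atoms$totalH[mol$atoms$element %in% c("N", "O")])
    c(sum(hetero) / sum(heavy), hbd)
  }, numeric(2)))
  data.frame(smiles = smiles, polarity = desc[, 1], hbd = as.integer(desc[, 2]),
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- surrogate targets ----------------------------------------------------

#' Surrogate target parameters
#'
#' The surrogate stands in for continuum-solvation calculations with a
#' transparent closed form that depends only on information visible to the
#' model: the net bond changes of the reaction and the composition of the
#' solvent. Per undirected bond-label weights act on (formed - broken)
#' counts, so a reverse reaction's structural term is exactly the negation
#' of the forward one; pi weights act likewise on bond-order changes.
#'
#' @param weights named kcal/mol weights per element-pair bond label.
#' @param piWeights named weights per label for bond-order changes
#'   (applied to new - old order).
#' @param hbondCoeff coefficient of the solvent-H-bond-donor x net-O-H term.
#' @param alpha enthalpy/free-energy scale (ddH = alpha x noiseless ddG +
#'   offset + noise); the default mirrors the ~1.4 magnitude ratio between
#'   the two targets in continuum-solvation reaction data.
#' @param offset additive enthalpy offset (kcal/mol).
#' @param sigma noise standard deviation (kcal/mol).
#' @return a \code{SurrogateParams} list.
#' @export
surrogateParams <- function(weights = c("C-H" = -2.4, "O-H" = 4.4,
                                        "C-C" = 2.0, "C-O" = 3.2,
                                        "O-O" = 3.6, "H-H" = -1.6),
                            piWeights = c("C-C" = -2.2, "C-O" = -3.0),
                            hbondCoeff = 1.0, alpha = 1.4, offset = 0,
                            sigma = 0.3) {
  if (sigma < 0) stopUsage("sigma must be >= 0")
  if (alpha <= 0) stopUsage("alpha must be > 0")
  structure(list(weights = weights, piWeights = piWeights,
                 hbondCoeff = hbondCoeff, alpha = alpha, offset = offset,
                 sigma = sigma),
            class = "SurrogateParams")
}

# Signed structural term: sum over labels of w * (formed - broken) plus
# pi-weight * net order change. Antisymmetric under reaction reversal.
surrogateStructure <- function(r, params) {
  sig <- bondChangeSignature(r)
  net <- function(lab) sum(sig$formed == lab) - sum(sig$broken == lab)
  labs <- unique(c(names(params$weights)))
  struct <- sum(vapply(labs, function(l) params$weights[[l]] * net(l),
                       numeric(1)))
  if (nrow(sig$order_changed) > 0) {
    for (k in seq_len(nrow(sig$order_changed))) {
      l <- sig$order_changed$label[k]
      w <- params$piWeights[l]
      if (!is.na(w))
        struct <- struct + w * (sig$order_changed$new[k] -
                                sig$order_changed$old[k])
    }
  }
  list(struct = struct, netOH = net("O-H"))
}

#' Surrogate targets for one reaction-solvent pair
#'
#' \deqn{\Delta\Delta G = polarity \times \sum_c w_c n_c(r) +
#'   h \times hbd \times n_{OH}(r) + \epsilon,\qquad
#'   \Delta\Delta H = \alpha \times \Delta\Delta G_{noiseless} + offset +
#'   \epsilon'}
#' with \eqn{\epsilon, \epsilon' \sim N(0, \sigma^2)} seeded stably per
#' (reaction key, direction, solvent, seed), so regeneration is exact.
#'
#' @param r a [MappedReaction-class].
#' @param solvent one row of [generateSolventLibrary()] (or a list with
#'   \code{smiles}, \code{polarity}, \code{hbd}).
#' @param params a [surrogateParams()].
#' @param seed global integer seed for the noise stream.
#' @return named numeric \code{c(ddG, ddH)} in kcal/mol.
#' @export
surrogateTargets <- function(r, solvent, params = surrogateParams(),
                             seed = 0L) {
  st <- surrogateStructure(r, params)
  noiseless <- solvent$polarity * st$struct +
    params$hbondCoeff * solvent$hbd * st$netOH
  eps <- if (params$sigma > 0) {
    recSeed <- stableHash(paste(reactionKey(r), directionTag(r),
                                solvent$smiles, seed, sep = "|"))
    withSeed(recSeed, stats::rnorm(2, 0, params$sigma))
  } else c(0, 0)
  c(ddG = noiseless + eps[1],
    ddH = params$alpha * noiseless + params$offset + eps[2])
}

#' Build a full synthetic reaction-solvent pair table
#'
#' Crosses \code{2 x nReactions} directed reactions with \code{nSolvents}
#' solvents and evaluates [surrogateTargets()] for every pair, yielding a
#' table with the same schema as a real dataset (plus \code{direction},
#' \code{reaction_key}, \code{family} and \code{provenance} columns) that
#' flows through curation, splitting and training end to end.
#'
#' @param nReactions number of undirected reactions.
#' @param nSolvents number of solvents.
#' @param params a [surrogateParams()].
#' @param seed integer seed (reaction/solvent sampling and noise).
#' @param provenance provenance tag stored on every record.
#' @return a pair-record data.frame with \code{2 x nReactions x nSolvents}
#'   rows.
#' @export
fixtureDataset <- function(nReactions, nSolvents,
                           params = surrogateParams(), seed = 0L,
                           provenance = "pretrain") {
  if (nReactions < 1L || nSolvents < 1L) stopUsage("sizes must be positive")
  rxns <- generateReactions(nReactions, seed)
  solv <- generateSolventLibrary(nSolvents, seed)
  nR <- length(rxns); nS <- nrow(solv)
  keys <- vapply(rxns, reactionKey, character(1))
  dirs <- vapply(rxns, directionTag, character(1))
  srcs <- vapply(rxns, sourceText, character(1))
  sts <- lapply(rxns, surrogateStructure, params = params)
  struct <- vapply(sts, `[[`, numeric(1), "struct")
  netOH <- vapply(sts, `[[`, numeric(1), "netOH")

  ri <- rep(seq_len(nR), each = nS)
  si <- rep(seq_len(nS), times = nR)
  noiseless <- solv$polarity[si] * struct[ri] +
    params$hbondCoeff * solv$hbd[si] * netOH[ri]
  n <- nR * nS
  eps <- matrix(0, n, 2)
  if (params$sigma > 0) {
    for (k in seq_len(n)) {
      recSeed <- stableHash(paste(keys[ri[k]], dirs[ri[k]],
                                  solv$smiles[si[k]], seed, sep = "|"))
      eps[k, ] <- withSeed(recSeed, stats::rnorm(2, 0, params$sigma))
    }
  }
  out <- data.frame(
    rxn_smiles = srcs[ri], solvent_smiles = solv$smiles[si],
    ddG_298 = noiseless + eps[, 1],
    ddH_298 = params$alpha * noiseless + params$offset + eps[, 2],
    direction = dirs[ri], reaction_key = keys[ri],
    family = names(rxns)[ri], provenance = provenance,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "extrasCols") <- character(0)
  out
}
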