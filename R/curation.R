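# Data curation and leakage-safe splitting. All operations are pure
# functions of (input records, parameters, seed). Record tables carry one
# row per reaction-solvent pair with columns rxn_smiles, solvent_smiles,
# ddG_298, ddH_298 and (after annotateRecords) reaction_key and direction.

#' Annotate records with reaction keys and direction tags
#'
#' Parses each distinct reaction SMILES once and adds \code{reaction_key}
#' (direction-agnostic identifier, [reactionKey()]) and \code{direction}
#' columns. Records already carrying both columns are returned unchanged.
#'
#' @param records pair-record data.frame.
#' @return the annotated data.frame.
#' @export
annotateRecords <- function(records) {
  if (all(c("reaction_key", "direction") %in% names(records)))
    return(records)
  rxnU <- unique(records$rxn_smiles)
  parsed <- lapply(rxnU, parseMappedReaction)
  keys <- vapply(parsed, reactionKey, character(1))
  records$reaction_key <- keys[match(records$rxn_smiles, rxnU)]
  if (!"direction" %in% names(records)) {
    # a direction tag is only meaningful relative to the paired reverse;
    # label the first-seen spelling of each key "forward"
    records$direction <- ifelse(records$rxn_smiles ==
      ave(records$rxn_smiles, records$reaction_key,
          FUN = function(x) x[1]), "forward", "reverse")
  }
  records
}

newFilterReport <- function(kept, removed, ids = list()) {
  structure(list(kept = kept, removed = removed, offending = ids),
            class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport: kept", x$kept, "\n")
  for (nm in names(x$removed))
    cat("  removed (", nm, "): ", x$removed[[nm]], "\n", sep = "")
  invisible(x)
}

#' Keep only reaction-solvent pairs computed in both directions
#'
#' A record survives only if its \code{(reaction_key, solvent_smiles)} pair
#' has at least one forward and one reverse record; unpaired records are
#' removed. This mirrors upstream cleaning where a reaction-solvent pair is
#' retained only when the calculation succeeded for both the forward and
#' reverse direction.
#'
#' @param records annotated pair-record data.frame (see [annotateRecords()]).
#' @return list with elements \code{records} (the kept rows) and
#'   \code{report} (a \code{FilterReport}).
#' @export
requireBothDirections <- function(records) {
  records <- annotateRecords(records)
  grp <- paste(records$reaction_key, records$solvent_smiles, sep = "\r")
  hasFwd <- ave(records$direction == "forward", grp, FUN = any)
  hasRev <- ave(records$direction == "reverse", grp, FUN = any)
  keep <- hasFwd & hasRev
  list(records = records[keep, , drop = FALSE],
       report = newFilterReport(sum(keep),
                                list(`missing-direction` = sum(!keep)),
                                list(`missing-direction` = which(!keep))))
}

#' Remove records with implausibly large targets
#'
#' Removes records with \code{|ddG_298| > g_cut} or \code{|ddH_298| > h_cut}
#' (strict inequality: boundary values are kept). Pre-training cleanup uses
#' 40 and 56 kcal/mol (14 standard deviations from the mean at the data's
#' sd of 2.76 and 3.92); fine-tuning data use the stricter 10 and
#' 18 kcal/mol. Idempotent.
#'
#' @param records pair-record data.frame.
#' @param g_cut,h_cut positive cutoffs in kcal/mol.
#' @return list with \code{records} and \code{report} as in
#'   [requireBothDirections()].
#' @export
filterOutliers <- function(records, g_cut = 40, h_cut = 56) {
  if (g_cut <= 0 || h_cut <= 0) stopUsage("cutoffs must be positive")
  bad <- abs(records$ddG_298) > g_cut | abs(records$ddH_298) > h_cut
  list(records = records[!bad, , drop = FALSE],
       report = newFilterReport(sum(!bad),
                                list(`magnitude-cutoff` = sum(bad)),
                                list(`magnitude-cutoff` = which(bad))))
}

#' Coverage-first subsampling of reaction-solvent pairs
#'
#' Draws \code{n} records such that, when feasible, every reaction key and
#' every solvent occurs at least once: a first pass picks one record per
#' uncovered reaction key, a second per uncovered solvent (uniformly among
#' candidates), and the remainder is filled uniformly without replacement.
#' If \code{n} is smaller than the number of distinct reaction keys the
#' coverage guarantee is infeasible and plain uniform sampling is used.
#'
#' @param records annotated pair-record data.frame.
#' @param n subset size (must not exceed \code{nrow(records)}).
#' @param seed integer seed; same seed, same subset.
#' @return the sampled records (row subset, original order preserved).
#' @export
coverageSample <- function(records, n, seed = 0L) {
  if (n > nrow(records)) stopUsage("n exceeds the number of records")
  records <- annotateRecords(records)
  withSeed(deriveSeed(seed, 301L), {
    keys <- unique(records$reaction_key)
    if (n < length(keys)) {
      pick <- sample(nrow(records), n)
      return(records[sort(pick), , drop = FALSE])
    }
    chosen <- integer(0)
    coveredSolv <- character(0)
    # one record per reaction key, preferring still-uncovered solvents so
    # solvent coverage comes for free whenever the grid allows it
    for (k in sample(keys)) {
      cand <- which(records$reaction_key == k)
      fresh <- cand[!records$solvent_smiles[cand] %in% coveredSolv]
      pickFrom <- if (length(fresh)) fresh else cand
      pick <- if (length(pickFrom) == 1L) pickFrom else sample(pickFrom, 1L)
      chosen <- c(chosen, pick)
      coveredSolv <- c(coveredSolv, records$solvent_smiles[pick])
    }
    # second pass for any solvent still uncovered, while room remains
    uncovered <- setdiff(unique(records$solvent_smiles), coveredSolv)
    for (s in sample(uncovered)) {
      if (length(chosen) >= n) break
      cand <- setdiff(which(records$solvent_smiles == s), chosen)
      if (length(cand) == 0L) next
      chosen <- c(chosen, if (length(cand) == 1L) cand else sample(cand, 1L))
    }
    rest <- setdiff(seq_len(nrow(records)), chosen)
    fill <- n - length(chosen)
    if (fill > 0L)
      chosen <- c(chosen, if (fill == length(rest)) rest
                          else sample(rest, fill))
    records[sort(chosen), , drop = FALSE]
  })
}

#' Polarity-weighted solvent sampling per reaction
#'
#' For each reaction key, draws up to \code{perReaction} distinct solvents
#' without replacement with probability proportional to the solvent weight
#' (defaults emphasize polar solvents: weight = 1 + 2 x heteroatom fraction
#' of the solvent, see [solventPolarityWeight()]). A post-pass swaps records
#' in so that every solvent present in the input appears at least once in
#' the output.
#'
#' @param records annotated pair-record data.frame.
#' @param perReaction target number of solvents per reaction (default 25).
#' @param weights named numeric vector of positive weights per solvent
#'   SMILES; missing solvents get the polarity-based default.
#' @param seed integer seed.
#' @return the sampled records.
#' @export
weightedSolventSample <- function(records, perReaction = 25L, weights = NULL,
                                  seed = 0L) {
  records <- annotateRecords(records)
  solvents <- unique(records$solvent_smiles)
  w <- vapply(solvents, solventPolarityWeight, numeric(1))
  names(w) <- solvents
  if (!is.null(weights)) {
    if (any(weights <= 0)) stopUsage("solvent weights must be positive")
    w[names(weights)] <- weights
  }
  withSeed(deriveSeed(seed, 302L), {
    chosen <- integer(0)
    for (k in unique(records$reaction_key)) {
      rows <- which(records$reaction_key == k)
      solK <- unique(records$solvent_smiles[rows])
      take <- min(perReaction, length(solK))
      pickSol <- if (take == length(solK)) solK
                 else sample(solK, take, prob = w[solK])
      chosen <- c(chosen, rows[records$solvent_smiles[rows] %in% pickSol])
    }
    # guarantee global solvent coverage by swapping one record in
    missing <- setdiff(solvents, records$solvent_smiles[chosen])
    for (s in missing) {
      cand <- which(records$solvent_smiles == s)
      add <- if (length(cand) == 1L) cand else sample(cand, 1L)
      # swap: drop one record of the same reaction whose solvent is
      # over-represented, keeping the size unchanged
      k <- records$reaction_key[add]
      tab <- table(records$solvent_smiles[chosen])
      dupSolv <- names(tab)[tab > 1L]
      drop <- which(records$reaction_key[chosen] == k &
                    records$solvent_smiles[chosen] %in% dupSolv)
      if (length(drop)) chosen <- chosen[-drop[1]]
      chosen <- c(chosen, add)
    }
    records[sort(unique(chosen)), , drop = FALSE]
  })
}

#' Default polarity proxy weight for a solvent
#'
#' \code{1 + 2 x (heteroatom count / heavy-atom count)}: 1 for alkanes, up
#' to 3 for water. A simple monotone proxy used when no explicit solvent
#' weights are supplied.
#'
#' @param smiles solvent SMILES.
#' @return a positive weight.
#' @export
solventPolarityWeight <- function(smiles) {
  mol <- parseSmiles(smiles)
  heavy <- mol$atoms$element != "H"
  hetero <- heavy & !mol$atoms$element %in% c("C", "H")
  1 + 2 * sum(hetero) / max(1L, sum(heavy))
}

roundHalfUp <- function(x) floor(x + 0.5)

groupedSplit <- function(records, groupCol, test_frac, val_frac, seed,
                         mode) {
  groups <- unique(records[[groupCol]])
  nTest <- max(1L, as.integer(roundHalfUp(test_frac * length(groups))))
  if (nTest >= length(groups))
    stopUsage("degenerate split: all groups selected for test")
  withSeed(deriveSeed(seed, 303L), {
    testGroups <- sample(groups, nTest)
    role <- rep("train", nrow(records))
    inTest <- records[[groupCol]] %in% testGroups
    role[inTest] <- "test"
    remaining <- which(!inTest)
    nVal <- as.integer(roundHalfUp(val_frac * length(remaining)))
    valIdx <- if (nVal > 0L) sample(remaining, nVal) else integer(0)
    role[valIdx] <- "val"
    data.frame(record_id = seq_len(nrow(records)), role = role,
               mode = mode, seed = seed)
  })
}

#' Leakage-safe grouped data splits
#'
#' \code{makeReactionSplit} samples \code{test_frac} of the distinct
#' reaction keys and moves every record of a chosen key -- both directions
#' and all solvents -- into the test set, so a reaction can never appear in
#' training while its reverse is in test. The remaining records are split
#' at the record level into train and validation (\code{val_frac} of the
#' remainder). \code{makeSolventSplit} does the same grouping by canonical
#' solvent. Fractional group counts round half-up with a minimum of one
#' group.
#'
#' @param records annotated pair-record data.frame.
#' @param test_frac fraction of groups routed to test (default 0.05).
#' @param val_frac fraction of the non-test records used for validation
#'   (default 0.2).
#' @param seed integer seed.
#' @return a split assignment data.frame with columns \code{record_id},
#'   \code{role} (train/val/test), \code{mode}, \code{seed}, aligned with
#'   \code{records}.
#' @export
makeReactionSplit <- function(records, test_frac = 0.05, val_frac = 0.2,
                              seed = 0L) {
  records <- annotateRecords(records)
  groupedSplit(records, "reaction_key", test_frac, val_frac, seed,
               "reaction")
}

#' @rdname makeReactionSplit
#' @export
makeSolventSplit <- function(records, test_frac = 0.05, val_frac = 0.2,
                             seed = 0L) {
  groupedSplit(records, "solvent_smiles", test_frac, val_frac, seed,
               "solvent")
}

#' @rdname makeReactionSplit
#' @param records,test_frac,val_frac as above.
#' @param k number of folds; each fold is an independent redraw with seed
#'   \code{seed + fold - 1} (not a partition).
#' @param mode \code{"reaction"}, \code{"solvent"} or \code{"random"}.
#' @return \code{makeFolds} returns a list of \code{k} split assignments.
#' @export
makeFolds <- function(records, k = 5L, mode = c("reaction", "solvent",
                                                "random"),
                      test_frac = 0.05, val_frac = 0.2, seed = 0L) {
  mode <- match.arg(mode)
  records <- annotateRecords(records)
  lapply(seq_len(k) - 1L, function(i) {
    s <- seed + i
    switch(mode,
      reaction = makeReactionSplit(records, test_frac, val_frac, s),
      solvent = makeSolventSplit(records, test_frac, val_frac, s),
      random = withSeed(deriveSeed(s, 304L), {
        n <- nrow(records)
        role <- rep("train", n)
        nTest <- as.integer(roundHalfUp(test_frac * n))
        testIdx <- if (nTest > 0L) sample(n, nTest) else integer(0)
        role[testIdx] <- "test"
        remaining <- setdiff(seq_len(n), testIdx)
        nVal <- as.integer(roundHalfUp(val_frac * length(remaining)))
        role[sample(remaining, nVal)] <- "val"
        data.frame(record_id = seq_len(n), role = role, mode = "random",
                   seed = s)
      }))
  })
}

#' Write / read a split manifest
#'
#' @param split a split assignment data.frame.
#' @param path CSV path.
#' @return \code{readSplitManifest} returns the data.frame.
#' @export
writeSplitManifest <- function(split, path) {
  utils::write.csv(split, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSplitManifest
#' @export
readSplitManifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
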