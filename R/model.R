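#' ModelBundle: a complete trained model
#'
#' Bundles the two independent message-passing encoders (one for the CGR of
#' the reaction, one for the solvent graph), the feed-forward regression
#' head mapping \code{[reaction embedding, solvent embedding, molecular
#' extras]} to the two targets, the target normalization statistics computed
#' from the training split, and a config fingerprint used to verify
#' checkpoint compatibility.
#'
#' @slot cgrEncoder,solventEncoder encoder parameter lists
#'   ([initEncoderParams()]).
#' @slot head feed-forward head parameter list.
#' @slot targetMean,targetSd length-2 numeric (ddG, ddH) training statistics.
#' @slot schema the [featureSchema()] used at featurization.
#' @slot extrasCols names of molecular extras columns the head expects.
#' @slot fingerprint character; hash of the architecture and schema version.
#' @export
setClass("ModelBundle",
         representation(cgrEncoder = "list", solventEncoder = "list",
                        head = "list", targetMean = "numeric",
                        targetSd = "numeric", schema = "list",
                        extrasCols = "character", fingerprint = "character"))

setValidity("ModelBundle", function(object) {
  if (length(object@targetMean) != 2L || length(object@targetSd) != 2L)
    return("target statistics must have length 2 (ddG, ddH)")
  if (any(object@targetSd <= 0)) return("target sd must be positive")
  if (object@head$outputs != 2L) return("head must have exactly 2 outputs")
  TRUE
})

setMethod("show", "ModelBundle", function(object) {
  cat("ModelBundle\n")
  cat("  CGR encoder:     hidden ", object@cgrEncoder$hidden, ", depth ",
      object@cgrEncoder$depth, "\n", sep = "")
  cat("  solvent encoder: hidden ", object@solventEncoder$hidden, ", depth ",
      object@solventEncoder$depth, "\n", sep = "")
  cat("  head: ", object@head$layers, " hidden layer(s), extras: ",
      if (length(object@extrasCols)) paste(object@extrasCols, collapse = ", ")
      else "none", "\n", sep = "")
  cat("  targets (kcal/mol): mean ", paste(signif(object@targetMean, 4),
      collapse = "/"), ", sd ", paste(signif(object@targetSd, 4),
      collapse = "/"), "\n", sep = "")
})

modelFingerprint <- function(cgrEncoder, solventEncoder, head, schema,
                             extrasCols) {
  as.character(stableHash(paste(
    schema$version, schema$atomWidth, schema$bondWidth,
    cgrEncoder$hidden, cgrEncoder$depth, cgrEncoder$atomWidth,
    cgrEncoder$bondWidth,
    solventEncoder$hidden, solventEncoder$depth, solventEncoder$atomWidth,
    head$layers, head$inputWidth, paste(extrasCols, collapse = ","),
    sep = "|")))
}

#' Construct a model bundle with freshly initialized weights
#'
#' @param schema a [featureSchema()].
#' @param hidden encoder hidden width.
#' @param depth message-passing depth.
#' @param ffnHidden,ffnLayers head hidden width and layer count.
#' @param extrasCols names of molecular extras columns (width adds to the
#'   head input).
#' @param seed integer seed controlling the random initialization.
#' @return a [ModelBundle-class] with unit target statistics (filled in by
#'   training).
#' @export
initModelBundle <- function(schema = featureSchema(), hidden = 300L,
                            depth = 3L, ffnHidden = 300L, ffnLayers = 2L,
                            extrasCols = character(0), seed = 0L) {
  aw <- schema$atomWidth; bw <- schema$bondWidth
  cgr <- initEncoderParams(2L * aw, 2L * bw, hidden, depth,
                           seed = deriveSeed(seed, 1L))
  sol <- initEncoderParams(aw, bw, hidden, depth,
                           seed = deriveSeed(seed, 2L))
  head <- initHeadParams(2L * hidden + length(extrasCols), ffnHidden,
                         ffnLayers, 2L, seed = deriveSeed(seed, 3L))
  new("ModelBundle", cgrEncoder = cgr, solventEncoder = sol, head = head,
      targetMean = c(0, 0), targetSd = c(1, 1), schema = unclass(schema),
      extrasCols = extrasCols,
      fingerprint = modelFingerprint(cgr, sol, head, schema, extrasCols))
}

normalizeTargets <- function(Y, mean, sd) sweep(sweep(Y, 2, mean), 2, sd, "/")
denormalizeTargets <- function(Y, mean, sd) sweep(sweep(Y, 2, sd, "*"), 2, mean, "+")

# Featurize the unique reactions and solvents of a record table once.
featurizeRecords <- function(records, schema) {
  rxnU <- unique(records$rxn_smiles)
  solU <- unique(records$solvent_smiles)
  cgrGraphs <- lapply(rxnU, function(s)
    buildCGR(parseMappedReaction(s), schema))
  solGraphs <- lapply(solU, function(s) buildMolGraph(s, schema))
  list(rxnU = rxnU, solU = solU,
       rid = match(records$rxn_smiles, rxnU),
       sid = match(records$solvent_smiles, solU),
       cgrGraphs = cgrGraphs, solGraphs = solGraphs)
}

extrasMatrix <- function(records, extrasCols) {
  if (length(extrasCols) == 0L)
    return(matrix(numeric(0), nrow(records), 0L))
  missing <- setdiff(extrasCols, names(records))
  if (length(missing))
    stopFeature("records lack extras column(s): ",
                paste(missing, collapse = ", "))
  m <- as.matrix(records[, extrasCols, drop = FALSE])
  if (any(!is.finite(m))) stopFeature("non-finite values in extras columns")
  m
}

# Core prediction on a record table; returns the normalized-scale head
# output de-normalized to kcal/mol.
predictCore <- function(bundle, records, feats = NULL) {
  schema <- structure(bundle@schema, class = "FeatureSchema")
  if (is.null(feats)) feats <- featurizeRecords(records, schema)
  embR <- encoderForward(packGraphs(feats$cgrGraphs), bundle@cgrEncoder)$emb
  embS <- encoderForward(packGraphs(feats$solGraphs), bundle@solventEncoder)$emb
  X <- cbind(embR[feats$rid, , drop = FALSE],
             embS[feats$sid, , drop = FALSE],
             extrasMatrix(records, bundle@extrasCols))
  Y <- headForward(X, bundle@head)$Y
  denormalizeTargets(Y, bundle@targetMean, bundle@targetSd)
}

#' Predict ddG/ddH of activation for reaction-solvent pairs
#'
#' @param bundle a trained [ModelBundle-class].
#' @param records a pair-record data.frame with at least \code{rxn_smiles}
#'   and \code{solvent_smiles} columns, plus any extras columns the bundle
#'   expects.
#' @return a data.frame with columns \code{ddG_pred}, \code{ddH_pred}
#'   (kcal/mol at 298 K).
#' @export
predictTable <- function(bundle, records) {
  Y <- predictCore(bundle, records)
  data.frame(ddG_pred = Y[, 1], ddH_pred = Y[, 2])
}

#' @describeIn predictTable predict a single reaction-solvent pair given as
#'   SMILES strings; \code{extras} is an optional named numeric vector.
#' @param rxn_smiles atom-mapped reaction SMILES.
#' @param solvent_smiles solvent SMILES.
#' @param extras named numeric vector of molecular extras.
#' @export
predictPair <- function(bundle, rxn_smiles, solvent_smiles, extras = NULL) {
  rec <- data.frame(rxn_smiles = rxn_smiles,
                    solvent_smiles = solvent_smiles)
  for (nm in names(extras)) rec[[nm]] <- extras[[nm]]
  out <- predictTable(bundle, rec)
  c(ddG_pred = out$ddG_pred[1], ddH_pred = out$ddH_pred[1])
}

#' Ensemble prediction: mean and spread over bundles
#'
#' @param bundles a non-empty list of [ModelBundle-class] objects.
#' @param records pair-record data.frame.
#' @return a data.frame with columns \code{ddG_pred}, \code{ddH_pred}
#'   (ensemble means) and \code{ddG_sd}, \code{ddH_sd} (sample standard
#'   deviation across ensemble members; 0 for a single bundle).
#' @export
ensemblePredict <- function(bundles, records) {
  if (length(bundles) == 0L) stopUsage("empty ensemble")
  preds <- lapply(bundles, function(b) as.matrix(predictTable(b, records)))
  arr <- simplify2array(preds)           # n x 2 x k
  mu <- apply(arr, c(1, 2), mean)
  sdv <- if (length(bundles) == 1L) matrix(0, nrow(records), 2L)
         else apply(arr, c(1, 2), stats::sd)
  data.frame(ddG_pred = mu[, 1], ddH_pred = mu[, 2],
             ddG_sd = sdv[, 1], ddH_sd = sdv[, 2])
}

# ---- checkpoint serialization ---------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON document holding the config fingerprint,
#' schema version, all weight arrays (named and shape-tagged), and the
#' target statistics. Loading verifies that the recomputed fingerprint
#' matches the stored one.
#'
#' @param bundle a [ModelBundle-class].
#' @param path file path to write to / read from.
#' @return \code{loadCheckpoint} returns the [ModelBundle-class];
#'   \code{saveCheckpoint} returns \code{path} invisibly.
#' @export
saveCheckpoint <- function(bundle, path) {
  enc <- function(p) lapply(p, function(x) {
    if (is.matrix(x)) list(shape = dim(x), data = as.numeric(x))
    else x
  })
  doc <- list(
    fingerprint = bundle@fingerprint,
    schema = bundle@schema,
    extrasCols = as.list(bundle@extrasCols),
    targetMean = bundle@targetMean, targetSd = bundle@targetSd,
    cgrEncoder = enc(bundle@cgrEncoder),
    solventEncoder = enc(bundle@solventEncoder),
    head = list(W = lapply(bundle@head$W,
                           function(w) list(shape = dim(w),
                                            data = as.numeric(w))),
                b = bundle@head$b,
                layers = bundle@head$layers,
                inputWidth = bundle@head$inputWidth,
                outputs = bundle@head$outputs))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  dec <- function(p, mats) {
    for (nm in mats)
      p[[nm]] <- matrix(p[[nm]]$data, p[[nm]]$shape[1], p[[nm]]$shape[2])
    for (nm in c("depth", "hidden", "atomWidth", "bondWidth"))
      if (!is.null(p[[nm]])) p[[nm]] <- as.integer(p[[nm]])
    p
  }
  cgr <- dec(doc$cgrEncoder, c("Wi", "Wh", "Wo"))
  sol <- dec(doc$solventEncoder, c("Wi", "Wh", "Wo"))
  W <- lapply(doc$head$W, function(w) matrix(w$data, w$shape[1], w$shape[2]))
  b <- doc$head$b
  if (is.matrix(b)) b <- lapply(seq_len(nrow(b)), function(i) b[i, ])
  head <- list(W = W, b = b, layers = as.integer(doc$head$layers),
               inputWidth = as.integer(doc$head$inputWidth),
               outputs = as.integer(doc$head$outputs))
  schema <- doc$schema
  schema$atomWidth <- as.integer(schema$atomWidth)
  schema$bondWidth <- as.integer(schema$bondWidth)
  extras <- as.character(unlist(doc$extrasCols))
  fp <- modelFingerprint(cgr, sol, head,
                         structure(schema, class = "FeatureSchema"), extras)
  if (!identical(fp, doc$fingerprint))
    stopUsage("checkpoint fingerprint mismatch: file ", doc$fingerprint,
              " vs recomputed ", fp)
  new("ModelBundle", cgrEncoder = cgr, solventEncoder = sol, head = head,
      targetMean = doc$targetMean, targetSd = doc$targetSd,
      schema = schema, extrasCols = extras, fingerprint = doc$fingerprint)
}
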