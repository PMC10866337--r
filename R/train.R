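#' Training configuration
#'
#' Loss is the mean squared error summed over the two normalized targets.
#' The learning rate ramps linearly from \code{lr/10} to \code{lr} over
#' \code{warmupEpochs}, then decays exponentially to
#' \code{lr * finalLrFactor} at \code{maxEpochs}. Early stopping is pure
#' best-epoch selection: training always runs to \code{maxEpochs} and the
#' parameter snapshot from the epoch with the lowest validation loss is
#' returned.
#'
#' @param maxEpochs maximum training epochs (use 80 for pre-training, 10 for
#'   fine-tuning).
#' @param batchSize minibatch size.
#' @param lr peak learning rate.
#' @param warmupEpochs warmup duration in epochs.
#' @param finalLrFactor ratio of final to peak learning rate.
#' @param dropout dropout probability on head hidden layers during training.
#' @param hidden,depth encoder hidden width and message-passing depth.
#' @param ffnHidden,ffnLayers head hidden width and hidden layer count.
#' @param ensembleSize models per fold in [buildEnsemble()].
#' @param seed master seed; every stochastic operation derives from it.
#' @return a \code{TrainConfig} list.
#' @export
trainConfig <- function(maxEpochs = 80L, batchSize = 64L, lr = 1e-3,
                        warmupEpochs = 2L, finalLrFactor = 0.1,
                        dropout = 0.05, hidden = 300L, depth = 3L,
                        ffnHidden = 300L, ffnLayers = 2L,
                        ensembleSize = 5L, seed = 0L) {
  if (maxEpochs < 1L) stopUsage("maxEpochs must be >= 1")
  if (batchSize < 1L) stopUsage("batchSize must be >= 1")
  structure(list(maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize), lr = lr,
                 warmupEpochs = warmupEpochs, finalLrFactor = finalLrFactor,
                 dropout = dropout, hidden = as.integer(hidden),
                 depth = as.integer(depth), ffnHidden = as.integer(ffnHidden),
                 ffnLayers = as.integer(ffnLayers),
                 ensembleSize = as.integer(ensembleSize),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

# ---- Adam over nested parameter lists -------------------------------------

adamInit <- function() list(t = 0L, m = list(), v = list())

# Update only the entries named in `grads`; everything else in `params`
# (depth, widths, ...) is untouched.
adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    keys <- names(g)
    if (is.null(keys)) keys <- seq_along(g)   # unnamed lists (head W/b)
    if (length(m) == 0L) {
      m <- vector("list", length(g)); v <- vector("list", length(g))
      names(m) <- names(g); names(v) <- names(g)
    }
    for (nm in keys) {
      if (is.list(g[[nm]])) {
        sub <- walk(p[[nm]], g[[nm]],
                    if (is.null(m[[nm]])) list() else m[[nm]],
                    if (is.null(v[[nm]])) list() else v[[nm]])
        p[[nm]] <- sub$p; m[[nm]] <- sub$m; v[[nm]] <- sub$v
      } else {
        gm <- g[[nm]]
        if (is.null(m[[nm]])) { m[[nm]] <- gm * 0; v[[nm]] <- gm * 0 }
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * gm
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * gm^2
        mhat <- m[[nm]] / (1 - beta1^state$t)
        vhat <- v[[nm]] / (1 - beta2^state$t)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    list(p = p, m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(t = state$t, m = res$m, v = res$v))
}

lrAt <- function(config, epoch, frac) {
  # epoch is 1-based; frac in [0,1) position within the epoch
  pos <- epoch - 1 + frac
  if (pos < config$warmupEpochs && config$warmupEpochs > 0) {
    config$lr * (0.1 + 0.9 * pos / config$warmupEpochs)
  } else {
    span <- max(config$maxEpochs - config$warmupEpochs, 1)
    decay <- (pos - config$warmupEpochs) / span
    config$lr * config$finalLrFactor^max(0, min(1, decay))
  }
}

bundleParams <- function(bundle) {
  list(cgr = bundle@cgrEncoder, sol = bundle@solventEncoder,
       head = bundle@head)
}

setBundleParams <- function(bundle, p) {
  bundle@cgrEncoder <- p$cgr
  bundle@solventEncoder <- p$sol
  bundle@head <- p$head
  bundle
}

# Forward + loss (+ gradients) for one batch of record indices.
batchPass <- function(idx, feats, Ynorm, Xextras, p, dropMasks = NULL,
                      computeGrads = TRUE) {
  ridU <- unique(feats$rid[idx]); sidU <- unique(feats$sid[idx])
  packR <- packGraphs(feats$cgrGraphs[ridU])
  packS <- packGraphs(feats$solGraphs[sidU])
  fwR <- encoderForward(packR, p$cgr, keepCache = computeGrads)
  fwS <- encoderForward(packS, p$sol, keepCache = computeGrads)
  ri <- match(feats$rid[idx], ridU); si <- match(feats$sid[idx], sidU)
  h <- p$cgr$hidden
  X <- cbind(fwR$emb[ri, , drop = FALSE], fwS$emb[si, , drop = FALSE],
             Xextras[idx, , drop = FALSE])
  fwH <- headForward(X, p$head, dropMasks, keepCache = computeGrads)
  resid <- fwH$Y - Ynorm[idx, , drop = FALSE]
  loss <- sum(resid^2) / length(idx)
  if (!computeGrads) return(list(loss = loss, Y = fwH$Y))
  dY <- 2 * resid / length(idx)
  bk <- headBackward(X, p$head, fwH$cache, dY)
  dEmbR <- scatterSum(bk$dX[, seq_len(h), drop = FALSE], ri, length(ridU))
  dEmbS <- scatterSum(bk$dX[, h + seq_len(h), drop = FALSE], si,
                      length(sidU))
  grads <- list(
    cgr = encoderBackward(packR, p$cgr, fwR$cache, dEmbR),
    sol = encoderBackward(packS, p$sol, fwS$cache, dEmbS),
    head = list(W = bk$dW, b = bk$db))
  list(loss = loss, grads = grads)
}

# Loss and per-target MAE on a record subset without dropout.
evalPass <- function(idx, feats, Ynorm, Xextras, p, targetSd) {
  out <- batchPass(idx, feats, Ynorm, Xextras, p, computeGrads = FALSE)
  resid <- out$Y - Ynorm[idx, , drop = FALSE]
  maeKcal <- colMeans(abs(resid)) * targetSd
  list(loss = out$loss, mae = maeKcal)
}

#' Train a model on a split record table
#'
#' Trains the dual-encoder model with Adam on the mean squared error of the
#' normalized targets, evaluating the validation loss after every epoch and
#' returning the parameters of the best-validation epoch. Target
#' normalization statistics are computed from the training records only and
#' stored in the bundle. When \code{init} is given (transfer learning), all
#' weights start from it and its target statistics are retained.
#'
#' @param records pair-record data.frame (see [readPairTable()]).
#' @param split a split assignment data.frame with a \code{role} column
#'   (\code{train}/\code{val}/\code{test}) aligned with \code{records}, from
#'   [makeReactionSplit()] or relatives.
#' @param config a [trainConfig()].
#' @param init optional [ModelBundle-class] to initialize from.
#' @param extrasCols molecular extras column names to feed the head.
#' @param keepSnapshots keep per-epoch parameter snapshots (used by
#'   [finetuneEpochSweep()]).
#' @return a list with elements \code{bundle} (best-epoch
#'   [ModelBundle-class]), \code{history} (per-epoch data.frame with
#'   \code{trainLoss}, \code{valLoss}, \code{valMAE_ddG}, \code{valMAE_ddH})
#'   and \code{bestEpoch}; with \code{keepSnapshots}, also \code{snapshots}.
#' @export
trainModel <- function(records, split, config = trainConfig(), init = NULL,
                       extrasCols = character(0), keepSnapshots = FALSE) {
  stopifnot(nrow(records) == nrow(split))
  trainIdx <- which(split$role == "train")
  valIdx <- which(split$role == "val")
  if (length(trainIdx) == 0L) stopUsage("empty training set")
  if (length(valIdx) == 0L) stopUsage("empty validation set")

  schema <- featureSchema()
  if (!is.null(init)) {
    bundle <- init
    extrasCols <- bundle@extrasCols
    schema <- structure(bundle@schema, class = "FeatureSchema")
  } else {
    bundle <- initModelBundle(schema, hidden = config$hidden,
                              depth = config$depth,
                              ffnHidden = config$ffnHidden,
                              ffnLayers = config$ffnLayers,
                              extrasCols = extrasCols,
                              seed = deriveSeed(config$seed, 101L))
    mu <- colMeans(records[trainIdx, c("ddG_298", "ddH_298")])
    sdv <- apply(records[trainIdx, c("ddG_298", "ddH_298")], 2, stats::sd)
    sdv[sdv < 1e-8] <- 1
    bundle@targetMean <- as.numeric(mu)
    bundle@targetSd <- as.numeric(sdv)
  }

  feats <- featurizeRecords(records, schema)
  Y <- as.matrix(records[, c("ddG_298", "ddH_298")])
  Ynorm <- normalizeTargets(Y, bundle@targetMean, bundle@targetSd)
  Xextras <- extrasMatrix(records, extrasCols)
  if (!is.null(init) &&
      bundle@head$inputWidth != 2L * bundle@cgrEncoder$hidden + ncol(Xextras))
    stopShape("init bundle expects ", bundle@head$inputWidth,
              " head inputs; records provide ",
              2L * bundle@cgrEncoder$hidden + ncol(Xextras))

  p <- bundleParams(bundle)
  state <- adamInit()
  nB <- ceiling(length(trainIdx) / config$batchSize)
  history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                        valLoss = numeric(0), valMAE_ddG = numeric(0),
                        valMAE_ddH = numeric(0))
  bestLoss <- Inf; bestP <- p; bestEpoch <- 0L
  snapshots <- if (keepSnapshots) vector("list", config$maxEpochs)

  for (epoch in seq_len(config$maxEpochs)) {
    ord <- withSeed(deriveSeed(config$seed, 7L, epoch), sample(trainIdx))
    epochLoss <- 0
    for (b in seq_len(nB)) {
      idx <- ord[((b - 1L) * config$batchSize + 1L):
                 min(b * config$batchSize, length(ord))]
      masks <- if (config$dropout > 0) {
        withSeed(deriveSeed(config$seed, 11L, epoch, b), {
          lapply(seq_len(p$head$layers), function(l) {
            w <- ncol(p$head$W[[l]])
            matrix(stats::rbinom(length(idx) * w, 1L, 1 - config$dropout) /
                     (1 - config$dropout), length(idx), w)
          })
        })
      }
      out <- batchPass(idx, feats, Ynorm, Xextras, p, masks)
      epochLoss <- epochLoss + out$loss * length(idx)
      up <- adamStep(p, out$grads, state, lrAt(config, epoch, (b - 1) / nB))
      p <- up$params; state <- up$state
    }
    ev <- evalPass(valIdx, feats, Ynorm, Xextras, p, bundle@targetSd)
    history <- rbind(history, data.frame(
      epoch = epoch, trainLoss = epochLoss / length(trainIdx),
      valLoss = ev$loss, valMAE_ddG = ev$mae[1], valMAE_ddH = ev$mae[2]))
    if (ev$loss < bestLoss) { bestLoss <- ev$loss; bestP <- p; bestEpoch <- epoch }
    if (keepSnapshots) snapshots[[epoch]] <- p
  }

  bundle <- setBundleParams(bundle, bestP)
  out <- list(bundle = bundle, history = history, bestEpoch = bestEpoch)
  if (keepSnapshots) out$snapshots <- snapshots
  out
}

#' Build an ensemble over folds and random initializations
#'
#' For each fold and each of \code{config$ensembleSize} members, trains one
#' model whose initialization (and batch shuffling) seed is derived
#' deterministically from \code{(config$seed, fold, member)}. Five folds
#' with five members give the 25-model ensemble used for final predictions
#' after fine-tuning.
#'
#' @param records pair-record data.frame.
#' @param folds a list of split assignments ([makeFolds()]).
#' @param config a [trainConfig()].
#' @param init optional [ModelBundle-class] (or list of bundles, one per
#'   fold x member, e.g. pre-trained models) to initialize from.
#' @param extrasCols molecular extras column names.
#' @return a list of [ModelBundle-class] of length
#'   \code{length(folds) * config$ensembleSize}, fold-major.
#' @export
buildEnsemble <- function(records, folds, config = trainConfig(),
                          init = NULL, extrasCols = character(0)) {
  if (length(folds) < 1L) stopUsage("at least one fold required")
  bundles <- list()
  k <- 0L
  for (f in seq_along(folds)) {
    for (i in seq_len(config$ensembleSize)) {
      k <- k + 1L
      cfg <- config
      cfg$seed <- deriveSeed(config$seed, f, i)
      ini <- if (is.null(init)) NULL
             else if (is.list(init) && !methods::is(init, "ModelBundle"))
               init[[k]]
             else init
      bundles[[k]] <- trainModel(records, folds[[f]], cfg, init = ini,
                                 extrasCols = extrasCols)$bundle
    }
  }
  bundles
}

#' Evaluate ensemble predictions against recorded targets
#'
#' Computes per-target MAE and RMSE of the ensemble-mean prediction in
#' kcal/mol. When \code{folds} is given, metrics are additionally computed
#' per fold over each fold's test records and summarized as mean and sd
#' across folds.
#'
#' @param bundles list of [ModelBundle-class] (or a single bundle).
#' @param records pair-record data.frame with \code{ddG_298}, \code{ddH_298}.
#' @param folds optional list of split assignments; fold f is evaluated with
#'   bundles \code{[(f-1)*perFold + 1 .. f*perFold]} on its test records.
#' @return a data.frame with columns \code{target}, \code{MAE}, \code{RMSE}
#'   (and \code{MAE_sd}, \code{RMSE_sd} when folds are given).
#' @export
evaluateModel <- function(bundles, records, folds = NULL) {
  if (methods::is(bundles, "ModelBundle")) bundles <- list(bundles)
  if (nrow(records) == 0L) stopUsage("no records to evaluate")
  metric <- function(bset, recs) {
    pred <- ensemblePredict(bset, recs)
    err <- cbind(pred$ddG_pred - recs$ddG_298, pred$ddH_pred - recs$ddH_298)
    data.frame(target = c("ddG", "ddH"),
               MAE = colMeans(abs(err)),
               RMSE = sqrt(colMeans(err^2)))
  }
  if (is.null(folds)) return(metric(bundles, records))
  perFold <- length(bundles) / length(folds)
  if (perFold != round(perFold))
    stopUsage("number of bundles is not a multiple of the number of folds")
  per <- lapply(seq_along(folds), function(f) {
    bset <- bundles[((f - 1L) * perFold + 1L):(f * perFold)]
    metric(bset, records[folds[[f]]$role == "test", , drop = FALSE])
  })
  mae <- sapply(per, function(d) d$MAE)
  rmse <- sapply(per, function(d) d$RMSE)
  data.frame(target = c("ddG", "ddH"),
             MAE = rowMeans(mae), MAE_sd = apply(mae, 1, stats::sd),
             RMSE = rowMeans(rmse), RMSE_sd = apply(rmse, 1, stats::sd))
}

#' Fine-tuning epoch sweep
#'
#' Re-runs fine-tuning at each maximum-epoch value of \code{epochGrid} from
#' the same pre-trained initialization and reports the fine-tune validation
#' MAE and the holdout MAE at the best-validation epoch within each budget.
#' The row for epoch 0 is the pre-trained model itself. Used to locate the
#' plateau where additional fine-tuning stops helping the holdout.
#'
#' @param pretrained a pre-trained [ModelBundle-class].
#' @param finetuneRecords,finetuneSplit fine-tuning data and its train/val
#'   split.
#' @param holdoutRecords records emulating the final test distribution.
#' @param epochGrid integer vector of maximum fine-tuning epochs (0 allowed).
#' @param config a [trainConfig()]; \code{maxEpochs} is overridden by the
#'   grid values.
#' @return data.frame with columns \code{maxEpochs}, \code{bestEpoch},
#'   \code{valLoss} (best validation loss within the budget, on the
#'   normalized scale), \code{valMAE_ddG}, \code{holdoutMAE_ddG},
#'   \code{holdoutMAE_ddH}.
#' @export
finetuneEpochSweep <- function(pretrained, finetuneRecords, finetuneSplit,
                               holdoutRecords, epochGrid,
                               config = trainConfig(maxEpochs = 10L)) {
  grid <- sort(unique(as.integer(epochGrid)))
  maxE <- max(grid)
  holdoutMAE <- function(bundle) {
    pred <- predictTable(bundle, holdoutRecords)
    c(mean(abs(pred$ddG_pred - holdoutRecords$ddG_298)),
      mean(abs(pred$ddH_pred - holdoutRecords$ddH_298)))
  }
  rows <- list()
  fit <- NULL
  if (maxE > 0L) {
    cfg <- config; cfg$maxEpochs <- maxE
    fit <- trainModel(finetuneRecords, finetuneSplit, cfg, init = pretrained,
                      keepSnapshots = TRUE)
  }
  for (e in grid) {
    if (e == 0L) {
      hm <- holdoutMAE(pretrained)
      pv <- evalPassBundle(pretrained, finetuneRecords, finetuneSplit)
      rows[[length(rows) + 1L]] <- data.frame(
        maxEpochs = 0L, bestEpoch = 0L, valLoss = pv$loss,
        valMAE_ddG = pv$mae,
        holdoutMAE_ddG = hm[1], holdoutMAE_ddH = hm[2])
    } else {
      sub <- fit$history[fit$history$epoch <= e, ]
      best <- sub$epoch[which.min(sub$valLoss)]
      bundle <- setBundleParams(pretrained, fit$snapshots[[best]])
      hm <- holdoutMAE(bundle)
      rows[[length(rows) + 1L]] <- data.frame(
        maxEpochs = e, bestEpoch = best,
        valLoss = min(sub$valLoss),
        valMAE_ddG = sub$valMAE_ddG[sub$epoch == best],
        holdoutMAE_ddG = hm[1], holdoutMAE_ddH = hm[2])
    }
  }
  do.call(rbind, rows)
}

# Validation loss (normalized-scale, as in training) and ddG MAE of a fixed
# bundle on the val records of a split.
evalPassBundle <- function(bundle, records, split) {
  valIdx <- which(split$role == "val")
  val <- records[valIdx, , drop = FALSE]
  pred <- predictTable(bundle, val)
  resid <- cbind(pred$ddG_pred - val$ddG_298, pred$ddH_pred - val$ddH_298)
  residNorm <- sweep(resid, 2, bundle@targetSd, "/")
  list(loss = sum(residNorm^2) / nrow(val),
       mae = mean(abs(resid[, 1])))
}
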