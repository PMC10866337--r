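# Training loop, transfer learning, ensembling, and evaluation metrics.

smallData <- function(nR = 8, nS = 4, sigma = 0, seed = 2) {
  fixtureDataset(nR, nS, surrogateParams(sigma = sigma), seed = seed)
}

test_that("the optimizer can drive training loss to near zero on a tiny set", {
  d <- smallData(3, 2)
  n <- nrow(d)
  split <- data.frame(record_id = seq_len(n),
                      role = c("train", "train", rep("val", n - 2)),
                      mode = "random", seed = 1)
  cfg <- quickConfig(maxEpochs = 400L, batchSize = 2L, lr = 5e-3)
  fit <- trainModel(d, split, cfg)
  expect_lt(min(fit$history$trainLoss), 1e-3)
})

test_that("training is deterministic under a fixed seed", {
  d <- smallData()
  split <- makeReactionSplit(d, test_frac = 0.2, val_frac = 0.2, seed = 3)
  cfg <- quickConfig(maxEpochs = 4L)
  h1 <- trainModel(d, split, cfg)$history
  h2 <- trainModel(d, split, cfg)$history
  expect_identical(h1, h2)
  h3 <- trainModel(d, split, quickConfig(maxEpochs = 4L, seed = 2L))$history
  expect_false(identical(h1$trainLoss, h3$trainLoss))
})

test_that("the returned bundle is the best-validation-epoch snapshot", {
  d <- smallData()
  split <- makeReactionSplit(d, test_frac = 0.2, val_frac = 0.25, seed = 5)
  fit <- trainModel(d, split, quickConfig(maxEpochs = 8L))
  expect_equal(fit$bestEpoch, which.min(fit$history$valLoss))
  # loss decreases over the first epochs (smoke property)
  expect_lt(fit$history$trainLoss[8], fit$history$trainLoss[1])
})

test_that("degenerate splits and shape mismatches are rejected", {
  d <- smallData()
  allTrain <- data.frame(record_id = seq_len(nrow(d)), role = "train",
                         mode = "random", seed = 1)
  expect_error(trainModel(d, allTrain, quickConfig()), class = "UsageError")
  noTrain <- allTrain; noTrain$role <- "val"
  expect_error(trainModel(d, noTrain, quickConfig()), class = "UsageError")
  expect_error(trainConfig(maxEpochs = 0), class = "UsageError")
  # init bundle with an incompatible head width
  split <- makeReactionSplit(d, test_frac = 0.2, val_frac = 0.2, seed = 1)
  wrong <- initModelBundle(hidden = 16, depth = 2, ffnHidden = 16,
                           extrasCols = c("e1", "e2"), seed = 1)
  expect_error(trainModel(d, split, quickConfig(), init = wrong),
               class = c("FeatureError"))
})

test_that("one epoch of fine-tuning changes the weights, and empty fine-tune data are rejected", {
  d <- smallData()
  split <- makeReactionSplit(d, test_frac = 0.2, val_frac = 0.2, seed = 2)
  pre <- trainModel(d, split, quickConfig(maxEpochs = 3L))$bundle
  ft <- trainModel(d, split, quickConfig(maxEpochs = 1L), init = pre)
  expect_gt(max(abs(ft$bundle@head$W[[1]] - pre@head$W[[1]])), 0)
  # target statistics are inherited from the pre-trained bundle
  expect_identical(ft$bundle@targetMean, pre@targetMean)
  empty <- d[0, ]
  emptySplit <- data.frame(record_id = integer(0), role = character(0),
                           mode = character(0), seed = integer(0))
  expect_error(trainModel(empty, emptySplit, quickConfig(), init = pre),
               class = "UsageError")
})

test_that("ensembles have fold x member structure with derived seeds", {
  d <- smallData(6, 3)
  folds <- makeFolds(d, k = 2, mode = "reaction", seed = 4)
  cfg <- quickConfig(maxEpochs = 2L, ensembleSize = 2L)
  bundles <- buildEnsemble(d, folds, cfg)
  expect_length(bundles, 4)
  # distinct seeds -> distinct weights
  expect_gt(max(abs(bundles[[1]]@head$W[[1]] - bundles[[2]]@head$W[[1]])), 0)
  one <- buildEnsemble(d, folds[1], quickConfig(maxEpochs = 2L,
                                                ensembleSize = 1L))
  expect_length(one, 1)
  expect_error(buildEnsemble(d, list(), cfg), class = "UsageError")
})

test_that("evaluation metrics match a direct loop and obey RMSE >= MAE", {
  d <- smallData(6, 3, sigma = 0.3)
  # constant-zero predictor: force the last head layer to zero with zero
  # target stats so predictions are exactly 0
  b <- initModelBundle(hidden = 8, depth = 1, ffnHidden = 8, seed = 3)
  nL <- length(b@head$W)
  b@head$W[[nL]] <- b@head$W[[nL]] * 0
  b@head$b[[nL]] <- c(0, 0)
  m <- evaluateModel(b, d)
  # brute-force oracle
  expect_equal(m$MAE[m$target == "ddG"], mean(abs(d$ddG_298)),
               tolerance = 1e-12)
  expect_equal(m$RMSE[m$target == "ddH"], sqrt(mean(d$ddH_298^2)),
               tolerance = 1e-12)
  expect_true(all(m$RMSE >= m$MAE))
  # perfect predictor via feeding targets back
  perfect <- data.frame(ddG_pred = d$ddG_298, ddH_pred = d$ddH_298)
  err <- cbind(perfect$ddG_pred - d$ddG_298, perfect$ddH_pred - d$ddH_298)
  expect_true(all(colMeans(abs(err)) == 0))
  expect_error(evaluateModel(b, d[0, ]), class = "UsageError")
})

test_that("fold-wise evaluation reports mean and spread across folds", {
  d <- smallData(8, 3, sigma = 0.2)
  folds <- makeFolds(d, k = 2, mode = "reaction", seed = 9)
  cfg <- quickConfig(maxEpochs = 2L, ensembleSize = 1L)
  bundles <- buildEnsemble(d, folds, cfg)
  m <- evaluateModel(bundles, d, folds = folds)
  expect_true(all(c("MAE", "MAE_sd", "RMSE", "RMSE_sd") %in% names(m)))
  expect_true(all(is.finite(m$MAE)))
})

test_that("the fine-tuning epoch sweep starts at the pretrained model and tracks best epochs", {
  d <- smallData(8, 3)
  split <- makeReactionSplit(d, test_frac = 0.15, val_frac = 0.2, seed = 6)
  pre <- trainModel(d, split, quickConfig(maxEpochs = 3L))$bundle
  holdout <- d[split$role == "test", ]
  sweep <- finetuneEpochSweep(pre, d, split, holdout, epochGrid = c(0, 2, 4),
                              config = quickConfig(maxEpochs = 4L))
  expect_equal(sweep$maxEpochs, c(0L, 2L, 4L))
  # epoch 0 row equals the pretrained performance
  predPre <- predictTable(pre, holdout)
  expect_equal(sweep$holdoutMAE_ddG[1],
               mean(abs(predPre$ddG_pred - holdout$ddG_298)),
               tolerance = 1e-12)
  # best epoch within each budget never exceeds the budget
  expect_true(all(sweep$bestEpoch <= sweep$maxEpochs))
  # best-epoch selection never worsens validation loss as the budget grows
  expect_true(all(diff(sweep$valLoss[-1]) <= 1e-12))
})
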