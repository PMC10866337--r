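# Cleaning filters, subsampling, and leakage-safe splits.

fakeRecords <- function(keys, solvents, directions = NULL) {
  g <- expand.grid(reaction_key = keys, solvent_smiles = solvents,
                   stringsAsFactors = FALSE)
  if (is.null(directions)) {
    g <- rbind(g, g)
    g$direction <- rep(c("forward", "reverse"), each = nrow(g) / 2)
  } else {
    g$direction <- directions
  }
  g$rxn_smiles <- paste0("rxn_", g$reaction_key)
  g$ddG_298 <- 0; g$ddH_298 <- 0
  g
}

test_that("the both-directions filter keeps exactly matched forward/reverse pairs", {
  recs <- data.frame(
    reaction_key = c("A", "A", "B", "C", "C"),
    solvent_smiles = c("s1", "s1", "s1", "s1", "s2"),
    direction = c("forward", "reverse", "forward", "forward", "reverse"),
    rxn_smiles = "x", ddG_298 = 0, ddH_298 = 0)
  out <- requireBothDirections(recs)
  # A kept (both directions, same solvent); B unpaired; C pair split across
  # different solvents -> all removed
  expect_equal(out$records$reaction_key, c("A", "A"))
  expect_equal(out$report$kept, 2)
  expect_equal(out$report$removed$`missing-direction`, 3)
  # every kept (key, solvent) pair has exactly one forward and one reverse
  grp <- paste(out$records$reaction_key, out$records$solvent_smiles)
  tab <- table(grp, out$records$direction)
  expect_true(all(tab == 1))
})

test_that("outlier filtering is strict at the boundary and idempotent", {
  recs <- data.frame(rxn_smiles = "x", solvent_smiles = "O",
                     ddG_298 = c(41, 40, -40.0001, 9, 0),
                     ddH_298 = c(0, 0, 0, 19, 56))
  out <- filterOutliers(recs, g_cut = 40, h_cut = 56)
  # |ddG|=41 and |ddG|=40.0001 removed; exactly 40 and |ddH|=56 kept
  expect_equal(out$records$ddG_298, c(40, 9, 0))
  expect_equal(out$report$removed$`magnitude-cutoff`, 2)
  # fine-tuning cuts: (9, 19) is removed by the enthalpy cut
  ft <- filterOutliers(recs, g_cut = 10, h_cut = 18)
  expect_false(any(ft$records$ddH_298 > 18))
  expect_false(9 %in% ft$records$ddG_298 & 19 %in% ft$records$ddH_298)
  # idempotence
  again <- filterOutliers(out$records, g_cut = 40, h_cut = 56)
  expect_identical(again$records, out$records)
  expect_equal(again$report$removed$`magnitude-cutoff`, 0)
  # empty input
  empty <- filterOutliers(recs[0, ], 40, 56)
  expect_equal(nrow(empty$records), 0)
  expect_equal(empty$report$kept, 0)
  expect_error(filterOutliers(recs, -1, 5), class = "UsageError")
})

test_that("coverage sampling touches every reaction and solvent when feasible", {
  recs <- fakeRecords(paste0("k", 1:10), paste0("s", 1:5),
                      directions = "forward")
  out <- coverageSample(recs, 10, seed = 3)
  expect_equal(nrow(out), 10)
  expect_setequal(unique(out$reaction_key), paste0("k", 1:10))
  expect_setequal(unique(out$solvent_smiles), paste0("s", 1:5))
  # n = |records| -> identity
  all <- coverageSample(recs, nrow(recs), seed = 1)
  expect_equal(nrow(all), nrow(recs))
  # determinism / seed sensitivity
  a <- coverageSample(recs, 20, seed = 5)
  b <- coverageSample(recs, 20, seed = 5)
  c <- coverageSample(recs, 20, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
  # infeasible coverage falls back to plain uniform sampling
  small <- coverageSample(recs, 5, seed = 2)
  expect_equal(nrow(small), 5)
  expect_error(coverageSample(recs, nrow(recs) + 1), class = "UsageError")
})

test_that("weighted solvent sampling tracks the weights within binomial noise", {
  nRxn <- 2000
  recs <- fakeRecords(paste0("k", seq_len(nRxn)), c("O", "C"),
                      directions = "forward")
  out <- weightedSolventSample(recs, perReaction = 1,
                               weights = c(O = 10, C = 1), seed = 8)
  expect_equal(nrow(out), nRxn)
  polarFrac <- mean(out$solvent_smiles == "O")
  p <- 10 / 11
  expect_lt(abs(polarFrac - p), 3 * sqrt(p * (1 - p) / nRxn) + 2 / nRxn)
  # per_reaction = available -> selects everything
  all <- weightedSolventSample(recs, perReaction = 2, seed = 1)
  expect_equal(nrow(all), nrow(recs))
  # deterministic under a fixed seed
  expect_identical(weightedSolventSample(recs, 1, c(O = 10, C = 1), seed = 4),
                   weightedSolventSample(recs, 1, c(O = 10, C = 1), seed = 4))
  # every solvent appears at least once even under extreme weights
  out2 <- weightedSolventSample(recs, perReaction = 1,
                                weights = c(O = 1e6, C = 1e-6), seed = 2)
  expect_true(all(c("O", "C") %in% out2$solvent_smiles))
  expect_error(weightedSolventSample(recs, 1, c(O = -1, C = 1)),
               class = "UsageError")
})

test_that("reaction splits quarantine whole reactions including reverses", {
  d <- fixtureDataset(20, 3, surrogateParams(sigma = 0), seed = 2)
  sp <- makeReactionSplit(d, test_frac = 0.05, val_frac = 0.2, seed = 1)
  expect_equal(nrow(sp), nrow(d))
  expect_setequal(unique(sp$role), c("train", "val", "test"))
  # 5% of 20 undirected reactions -> exactly 1 reaction = 6 records in test
  expect_equal(sum(sp$role == "test"), 6)
  testKeys <- unique(d$reaction_key[sp$role == "test"])
  trainvalKeys <- unique(d$reaction_key[sp$role != "test"])
  expect_length(intersect(testKeys, trainvalKeys), 0)
  # forward in train while reverse in test is impossible
  dirTab <- table(d$reaction_key, sp$role == "test")
  expect_true(all(dirTab[, 1] == 0 | dirTab[, 2] == 0))
})

test_that("solvent splits quarantine whole solvents and round half-up", {
  d <- fixtureDataset(10, 40, surrogateParams(sigma = 0), seed = 6)
  sp <- makeSolventSplit(d, test_frac = 0.05, val_frac = 0.2, seed = 2)
  testSolv <- unique(d$solvent_smiles[sp$role == "test"])
  otherSolv <- unique(d$solvent_smiles[sp$role != "test"])
  expect_length(intersect(testSolv, otherSolv), 0)
  expect_equal(length(testSolv), 2)   # 0.05 * 40 -> 2 solvents
  # reproducibility
  expect_identical(sp, makeSolventSplit(d, 0.05, 0.2, seed = 2))
})

test_that("folds are independent seeded redraws satisfying the invariants", {
  d <- fixtureDataset(25, 4, surrogateParams(sigma = 0), seed = 8)
  folds <- makeFolds(d, k = 5, mode = "reaction", seed = 10)
  expect_length(folds, 5)
  for (f in folds) {
    testKeys <- unique(d$reaction_key[f$role == "test"])
    expect_length(intersect(testKeys,
                            unique(d$reaction_key[f$role != "test"])), 0)
  }
  testSets <- vapply(folds, function(f) paste(which(f$role == "test"),
                                              collapse = ","), character(1))
  expect_gt(length(unique(testSets)), 1)
  one <- makeFolds(d, k = 1, mode = "reaction", seed = 3)
  expect_length(one, 1)
})

test_that("degenerate splits are rejected", {
  d <- fixtureDataset(2, 2, surrogateParams(sigma = 0), seed = 1)
  expect_error(makeReactionSplit(d, test_frac = 0.99, seed = 1),
               class = "UsageError")
})

test_that("split manifests round-trip through CSV", {
  d <- fixtureDataset(5, 2, surrogateParams(sigma = 0), seed = 3)
  sp <- makeReactionSplit(d, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSplitManifest(sp, path)
  back <- readSplitManifest(path)
  expect_equal(back$role, sp$role)
  expect_equal(back$record_id, sp$record_id)
})
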