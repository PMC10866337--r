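# Message-passing encoder, regression head, and checkpoint round trips.

randomTestSmiles <- c("CCO", "CC(C)O", "C=CC", "CC(=O)N", "c1ccccc1",
                      "OCCO", "CC#N", "C1CCOC1", "CC(C)(C)C", "COC")

test_that("vectorized encoding matches the dense arc-by-arc oracle on 10 graphs", {
  s <- featureSchema()
  for (i in seq_along(randomTestSmiles)) {
    g <- buildMolGraph(randomTestSmiles[i], s)
    p <- initEncoderParams(s$atomWidth, s$bondWidth, hidden = 9, depth = 3,
                           seed = i)
    expect_equal(encodeGraph(g, p), denseEncodeOracle(g, p),
                 tolerance = 1e-6)
  }
})

test_that("a single-atom graph embeds through the atom transform alone", {
  s <- featureSchema()
  g <- buildMolGraph("O", s)
  p <- initEncoderParams(s$atomWidth, s$bondWidth, hidden = 6, depth = 3,
                         seed = 2)
  manual <- pmax(drop(c(atomFeatures(g)[1, ], numeric(6)) %*% p$Wo) + p$bo, 0)
  expect_equal(encodeGraph(g, p), manual, tolerance = 1e-12)
})

test_that("embeddings are invariant under atom-order permutation", {
  s <- featureSchema()
  p <- initEncoderParams(s$atomWidth, s$bondWidth, hidden = 12, depth = 3,
                         seed = 7)
  pairs <- list(c("CCO", "OCC"), c("CC(C)O", "OC(C)C"),
                c("c1ccccc1", "c1ccccc1"), c("CC(=O)N", "NC(C)=O"))
  for (pr in pairs) {
    e1 <- encodeGraph(buildMolGraph(pr[1], s), p)
    e2 <- encodeGraph(buildMolGraph(pr[2], s), p)
    expect_equal(e1, e2, tolerance = 1e-6)
  }
})

test_that("at depth 0 the embedding ignores bond features entirely", {
  s <- featureSchema()
  g <- buildMolGraph("CCO", s)
  p0 <- initEncoderParams(s$atomWidth, s$bondWidth, hidden = 8, depth = 0,
                          seed = 3)
  e1 <- encodeGraph(g, p0)
  g2 <- g
  g2@arcFeat <- g2@arcFeat + 10   # perturb bond features
  expect_equal(encodeGraph(g2, p0), e1, tolerance = 1e-12)
  # at depth >= 1 the same perturbation must matter
  p1 <- initEncoderParams(s$atomWidth, s$bondWidth, hidden = 8, depth = 1,
                          seed = 3)
  expect_gt(max(abs(encodeGraph(g2, p1) - encodeGraph(g, p1))), 1e-6)
})

test_that("analytic gradients match finite differences", {
  s <- featureSchema()
  graphs <- lapply(c("CCO", "C=CC"), buildMolGraph, schema = s)
  pack <- kinsolv:::packGraphs(graphs)
  p <- initEncoderParams(s$atomWidth, s$bondWidth, hidden = 5, depth = 2,
                         seed = 11)
  G <- matrix(withr::with_seed(1, rnorm(10)), 2, 5)
  fw <- kinsolv:::encoderForward(pack, p, keepCache = TRUE)
  gr <- kinsolv:::encoderBackward(pack, p, fw$cache, G)
  lossOf <- function(pp) sum(kinsolv:::encoderForward(pack, pp)$emb * G)
  eps <- 1e-6
  for (nm in c("Wi", "bi", "Wh", "Wo", "bo")) {
    picks <- withr::with_seed(2, sample(length(p[[nm]]),
                                        min(25, length(p[[nm]]))))
    for (k in picks) {
      pp <- p; pp[[nm]][k] <- p[[nm]][k] + eps; up <- lossOf(pp)
      pp[[nm]][k] <- p[[nm]][k] - eps; dn <- lossOf(pp)
      expect_equal(gr[[nm]][k], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("a zero-weight head predicts the de-normalized bias for any input", {
  b <- initModelBundle(hidden = 8, depth = 1, ffnHidden = 8, ffnLayers = 1,
                       seed = 1)
  nL <- length(b@head$W)
  b@head$W[[nL]] <- b@head$W[[nL]] * 0
  b@head$b[[nL]] <- c(0.25, -0.5)
  b@targetMean <- c(1, 2); b@targetSd <- c(2, 4)
  p1 <- predictPair(b, "[CH3:1][H:2].[O:3][H:4]>>[CH3:1].[H:2][O:3][H:4]", "O")
  p2 <- predictPair(b, "[CH4:1]>>[CH4:1]", "CCO")
  # only if the last layer is zeroed is the output input-independent
  expect_equal(unname(p1), c(1 + 0.25 * 2, 2 - 0.5 * 4))
  expect_equal(p1, p2)
})

test_that("predictions are deterministic and invariant to solvent SMILES spelling", {
  b <- initModelBundle(hidden = 10, depth = 2, ffnHidden = 10, seed = 42)
  rxn <- "[CH3:1][H:2].[O:3][H:4]>>[CH3:1].[H:2][O:3][H:4]"
  p1 <- predictPair(b, rxn, "CCO")
  p2 <- predictPair(b, rxn, "CCO")
  expect_identical(p1, p2)
  p3 <- predictPair(b, rxn, "OCC")
  expect_equal(p1, p3, tolerance = 1e-6)
  p4 <- predictPair(b, rxn, "CCCO")
  expect_gt(max(abs(p4 - p1)), 1e-6)
})

test_that("target normalization round-trips", {
  Y <- matrix(withr::with_seed(3, rnorm(20)), 10, 2)
  mu <- c(0.3, -1.2); sdv <- c(1.7, 2.4)
  back <- kinsolv:::denormalizeTargets(
    kinsolv:::normalizeTargets(Y, mu, sdv), mu, sdv)
  expect_equal(back, Y, tolerance = 1e-9)
})

test_that("ensembles average predictions and report spread", {
  d <- fixtureDataset(2, 2, surrogateParams(sigma = 0), seed = 9)
  b1 <- initModelBundle(hidden = 6, depth = 1, ffnHidden = 6, seed = 1)
  b2 <- initModelBundle(hidden = 6, depth = 1, ffnHidden = 6, seed = 2)
  one <- ensemblePredict(list(b1), d)
  expect_true(all(one$ddG_sd == 0))
  expect_equal(one$ddG_pred, predictTable(b1, d)$ddG_pred)
  five <- ensemblePredict(rep(list(b1), 5), d)
  expect_equal(five$ddG_pred, one$ddG_pred, tolerance = 1e-12)
  expect_true(all(five$ddG_sd < 1e-12))
  mix <- ensemblePredict(list(b1, b2), d)
  expect_equal(mix$ddG_pred,
               (predictTable(b1, d)$ddG_pred + predictTable(b2, d)$ddG_pred) / 2)
  expect_true(any(mix$ddG_sd > 0))
  expect_error(ensemblePredict(list(), d), class = "UsageError")
})

test_that("checkpoints round-trip weights exactly and verify their fingerprint", {
  b <- initModelBundle(hidden = 7, depth = 2, ffnHidden = 5, ffnLayers = 2,
                       seed = 13)
  b@targetMean <- c(0.5, 1.5); b@targetSd <- c(1.1, 2.2)
  path <- withr::local_tempfile(fileext = ".json")
  saveCheckpoint(b, path)
  b2 <- loadCheckpoint(path)
  d <- data.frame(rxn_smiles = "[CH4:1]>>[CH4:1]", solvent_smiles = "O")
  expect_equal(predictTable(b2, d), predictTable(b, d), tolerance = 1e-12)
  expect_identical(b2@fingerprint, b@fingerprint)
  # corrupt the stored fingerprint -> load must fail
  doc <- jsonlite::read_json(path)
  doc$fingerprint <- "0"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(loadCheckpoint(path), class = "UsageError")
})

test_that("mismatched feature widths raise a shape error", {
  s <- featureSchema()
  g <- buildMolGraph("CCO", s)
  p <- initEncoderParams(s$atomWidth + 3L, s$bondWidth, hidden = 4,
                         depth = 1, seed = 1)
  expect_error(encodeGraph(g, p), class = "ShapeError")
})
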