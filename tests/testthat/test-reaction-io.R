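# Parsing, validation, canonicalization and classification of atom-mapped
# reactions, plus pair-table round trips.

test_that("a mapped bimolecular reaction parses with a full map bijection", {
  r <- toyAbstraction()
  expect_s4_class(r, "MappedReaction")
  expect_equal(nrow(mapPairs(r)), 4)
  expect_equal(directionTag(r), "forward")
  expect_equal(reactantGraph(r)$component_count, 2L)
})

test_that("identity reactions parse and carry an empty bond-change signature", {
  r <- toyIdentity()
  sig <- bondChangeSignature(r)
  expect_length(sig$formed, 0)
  expect_length(sig$broken, 0)
  expect_equal(nrow(sig$order_changed), 0)
  expect_equal(formatSignature(sig), "")
})

test_that("malformed reactions raise typed errors", {
  expect_error(parseMappedReaction("[CH4:1]>>[CH3:1]"), class = "BalanceError")
  expect_error(parseMappedReaction("[CH4:1]>>[CH4:2]"), class = "MappingError")
  expect_error(parseMappedReaction("[CH4:1].[CH4:1]>>[CH4:1].[CH4:1]"),
               class = "MappingError")
  expect_error(parseMappedReaction("CC>>CC"), class = "MappingError")
  expect_error(parseMappedReaction("[CH4:1]>[CH4:1]"), class = "ParseError")
  expect_error(parseMappedReaction("not-smiles>>also-not"),
               class = "ParseError")
})

test_that("reversal swaps sides, flips the tag, and is an involution", {
  r <- toyAbstraction()
  rr <- reverseReaction(r)
  expect_equal(directionTag(rr), "reverse")
  expect_identical(reactantGraph(rr)$atoms, productGraph(r)$atoms)
  back <- reverseReaction(rr)
  expect_identical(sourceText(back), sourceText(r))
  expect_identical(reactantGraph(back)$atoms, reactantGraph(r)$atoms)
  # signature of the reverse swaps formed and broken
  sig <- bondChangeSignature(r); sigR <- bondChangeSignature(rr)
  expect_identical(sig$formed, sigR$broken)
  expect_identical(sig$broken, sigR$formed)
})

test_that("toy H-abstraction signature renders with the +formed/-broken convention", {
  sig <- bondChangeSignature(toyAbstraction())
  expect_identical(sig$formed, "O-H")
  expect_identical(sig$broken, "C-H")
  expect_identical(formatSignature(sig), "+O-H, -C-H")
})

test_that("reaction keys are invariant to direction and atom-map renumbering", {
  pool <- reactionPool()
  some <- pool$rxn_smiles[seq(1, nrow(pool), by = 11)]
  for (s in some) {
    r <- parseMappedReaction(s)
    expect_identical(reactionKey(r), reactionKey(reverseReaction(r)))
    for (seed in 1:3) {
      r2 <- parseMappedReaction(renumberMaps(s, seed))
      expect_identical(reactionKey(r2), reactionKey(r))
    }
  }
})

test_that("distinct template reactions get pairwise distinct keys", {
  pool <- reactionPool()
  keys <- pool$reaction_key
  expect_equal(anyDuplicated(keys), 0)
  # same reactants, different products -> different keys
  a <- parseMappedReaction("[CH2:1]=[CH2:2].[OH:3]>>[CH2:1]([OH:3])[CH2:2]")
  b <- parseMappedReaction(
    "[CH2:1]=[CH2:2].[OH:3]>>[CH2:1]=[CH2:2].[OH:3]")
  expect_false(reactionKey(a) == reactionKey(b))
})

test_that("family templates classify the three radical families and fall back to other", {
  expect_equal(classifyReactionFamily(toyAbstraction()), "H-abstraction")
  mig <- parseMappedReaction(
    "[CH2:1]([H:3])[CH2:2][O:4][H:5]>>[CH2:1]([H:3])([H:5])[CH2:2][O:4]")
  expect_equal(classifyReactionFamily(mig), "H-migration")
  add <- parseMappedReaction("[CH2:1]=[CH2:2].[CH3:3]>>[CH2:1]([CH3:3])[CH2:2]")
  expect_equal(classifyReactionFamily(add), "R-addition")
  # reverse inherits the forward label (beta-scission -> R-addition)
  expect_equal(classifyReactionFamily(reverseReaction(add)), "R-addition")
  # identity: no template matches
  expect_equal(classifyReactionFamily(toyIdentity()), "other")
})

test_that("pair tables round-trip through CSV including extras columns", {
  d <- fixtureDataset(3, 3, surrogateParams(sigma = 0.2), seed = 4)
  d$dGsolv_R <- rnorm(nrow(d)); d$dHsolv_R <- rnorm(nrow(d))
  d$dGsolv_P <- rnorm(nrow(d)); d$dHsolv_P <- rnorm(nrow(d))
  attr(d, "extrasCols") <- c("dGsolv_R", "dHsolv_R", "dGsolv_P", "dHsolv_P")
  path <- withr::local_tempfile(fileext = ".csv")
  writePairTable(d, path)
  back <- readPairTable(path)
  expect_identical(attr(back, "extrasCols"),
                   c("dGsolv_R", "dHsolv_R", "dGsolv_P", "dHsolv_P"))
  expect_identical(back$rxn_smiles, d$rxn_smiles)
  expect_equal(back$ddG_298, d$ddG_298, tolerance = 1e-15)
  expect_equal(back$dGsolv_P, d$dGsolv_P, tolerance = 1e-15)
})

test_that("pair-table schema errors and permissive mode behave as specified", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("rxn_smiles,solvent_smiles,ddG_298", path)
  expect_error(readPairTable(path), class = "SchemaError")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rxn_smiles,solvent_smiles,ddG_298,ddH_298",
               "\"[CH4:1]>>[CH4:1]\",O,0.5,1.0",
               "\"[CH4:1]>>[CH4:1]\",O,NA,1.0"), path2)
  expect_error(readPairTable(path2), class = "SchemaError")
  ok <- readPairTable(path2, permissive = TRUE)
  expect_equal(nrow(ok), 1)
  expect_equal(attr(ok, "rejected")$line, 3L)

  # empty table with header -> zero records
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("rxn_smiles,solvent_smiles,ddG_298,ddH_298", path3)
  expect_equal(nrow(readPairTable(path3)), 0)

  # schema remapping of alternate column spellings
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rxn,solvent,dG,dH", "\"[CH4:1]>>[CH4:1]\",O,0.1,0.2"), path4)
  remap <- readPairTable(path4, schema = c(rxn = "rxn_smiles",
                                           solvent = "solvent_smiles",
                                           dG = "ddG_298", dH = "ddH_298"))
  expect_equal(remap$ddH_298, 0.2)
})

test_that("validate mode catches unparsable reactions at load time", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rxn_smiles,solvent_smiles,ddG_298,ddH_298",
               "\"[CH4:1]>>[CH3:1]\",O,0.1,0.2"), path)
  expect_error(readPairTable(path, validate = TRUE), class = "SchemaError")
  perm <- readPairTable(path, validate = TRUE, permissive = TRUE)
  expect_equal(nrow(perm), 0)
})
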