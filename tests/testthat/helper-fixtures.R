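# Shared fixtures built in code.

# toy bimolecular H-abstraction: methane + hydroxyl -> methyl + water
toyAbstraction <- function() {
  parseMappedReaction("[CH3:1][H:2].[O:3][H:4]>>[CH3:1].[H:2][O:3][H:4]")
}

toyIdentity <- function() parseMappedReaction("[CH4:1]>>[CH4:1]")

# small config for fast training tests
quickConfig <- function(maxEpochs = 10L, seed = 1L, batchSize = 16L,
                        lr = 3e-3, ...) {
  trainConfig(maxEpochs = maxEpochs, batchSize = batchSize, lr = lr,
              hidden = 16L, depth = 2L, ffnHidden = 16L, ffnLayers = 1L,
              dropout = 0, seed = seed, ...)
}

# random renumbering of the atom maps of a mapped reaction SMILES
renumberMaps <- function(text, seed) {
  maps <- unique(as.integer(
    regmatches(text, gregexpr("(?<=:)[0-9]+", text, perl = TRUE))[[1]]))
  neu <- withr::with_seed(seed, sample(100:999, length(maps)))
  out <- text
  # two-phase rewrite to avoid collisions
  for (i in seq_along(maps))
    out <- gsub(paste0(":", maps[i], "]"), paste0(":tmp", i, "]"), out,
                fixed = TRUE)
  for (i in seq_along(maps))
    out <- gsub(paste0(":tmp", i, "]"), paste0(":", neu[i], "]"), out,
                fixed = TRUE)
  out
}
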