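---
title: "Predicting kinetic solvent effects from condensed graphs of reaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting kinetic solvent effects from condensed graphs of reaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinsolv)
```

## What the model predicts

`kinsolv` predicts, for one reaction–solvent pair, the solvation free
energy and solvation enthalpy of activation at 298 K
(`ddG‡_solv`, `ddH‡_solv`, kcal/mol): the difference in solvation energy
between the transition state and the reactant(s) (summed over all
reactants for a bimolecular step), on a 1 M gas / 1 M solution standard
state. These two numbers carry the kinetic solvent effect:

* `log10RateRatioLiqGas()` converts `ddG‡_solv` into
  `log10(k_liq/k_gas) = −ddG‡/(RT ln 10)`; the sign convention is that a
  positive `ddG‡_solv` (TS destabilised relative to reactants) slows the
  liquid-phase reaction. The convention is pinned by the magnitude
  anchors: 40 kcal/mol corresponds to about 29 orders of magnitude at
  298 K and 10 kcal/mol to about 7.
* `log10RateRatioTwoSolvents()` gives solvent-to-solvent rate ratios by
  exact additivity of the gas/liquid form.
* `extrapolateDdG()` moves `ddG‡` to another temperature with the linear
  (constant `ddH`/`ddS`) Gibbs–Helmholtz form
  `ddG(T) = ddH298 − T (ddH298 − ddG298)/298`, trusted for roughly
  250–400 K; outside that window the function warns but still answers.
* `ddHFromGradient()` is the inverse tool used when only free energies
  are available: a central finite difference over 297/298/299 K. For any
  free-energy profile linear in T the estimator is exact, and the
  extrapolate→gradient round trip reproduces `ddH298` to numerical
  precision — a property the test suite asserts at 1e-9.

The model never sees 3D geometry: the transition state is represented
only implicitly, through what changes between reactant and product
graphs.

## Representation

An atom-mapped reaction SMILES is parsed strictly: every written atom
must carry a map number, the map numbers must form a bijection between
the sides, mapped pairs must agree in element, and the reaction must be
balanced (heavy atoms and hydrogens, implicit hydrogens counted).
Violations raise typed errors rather than warnings, and the permissive
table-reading mode only ever drops offending rows — it never repairs
them. Hydrogens stay implicit except those written explicitly (in
practice: the transferred hydrogen of an H-abstraction or H-migration),
which become graph nodes and keep their map numbers. Whether reacting
hydrogens are written explicitly is therefore a property of the input
data, not a hidden switch; the templated generator always writes them
explicitly so that hydrogen transfers are visible in the graph.

The condensed graph of reaction (CGR) superposes the two sides over the
map bijection. Each node's feature vector is
`[reactant features, product − reactant]`; each bond present on either
side contributes `[reactant bond features, product − reactant]`, with an
absent side encoded as a null-bond vector (zeros plus a set null flag).
Two consequences are used as correctness oracles: an identity reaction
has all difference blocks exactly zero, and reversing a reaction negates
every difference block.

Atom features are the standard graph-network vocabulary: element one-hot
over {H, C, N, O, S, other}, degree 0–5, formal charge −2..+2,
hybridization, aromatic flag, total hydrogen count 0–4, and scaled
atomic mass (28 columns). Bond features are bond-order one-hot
{single, double, triple, aromatic}, conjugation, ring membership, and
the null flag (7 columns). An optional additional atom block
(radical-electron count, smallest ring size, lone pairs, H-bond
donor/acceptor flags, scaled electronegativity) is available but off by
default, since the default set already spans what the targets depend on.
Chirality is deliberately not encoded: the targets derive from 2D
structure.

## Encoders and head

Reaction and solvent are encoded by two structurally identical but
entirely separate directed message-passing encoders (no weight sharing —
the two inputs live in different feature spaces). Messages live on
directed arcs; an arc's state is initialised from
`[source-atom features, bond features]`, and each of `depth` updates
aggregates the incoming messages at the arc's source *excluding its own
reverse arc* — the defining property of the directed scheme, which stops
messages from bouncing straight back. Every update keeps a skip
connection to the initial arc state. Atom states combine raw atom
features with incident arc messages, and the graph embedding is the mean
over atoms (mean rather than sum keeps embeddings comparable between
unimolecular and bimolecular reactions). `depth = 0` is defined as "no
bond message passing at all": the embedding then depends only on atom
features, which the tests exploit as a degenerate-case oracle.

The two embeddings, plus any molecular extras (e.g. the four
reactant/product solvation energy columns), feed a feed-forward network
with ReLU hidden layers and two linear outputs. Targets are standardised
with training-split statistics only; the statistics are stored in the
model bundle so predictions de-normalise consistently and a fine-tuned
model keeps its pre-training normalisation.

Defaults (all overridable in `trainConfig()`): hidden width 300, depth
3, two hidden head layers of 300, dropout 0.05 — conventional values for
this architecture family. The desk-scale experiments in this package use
hidden 64 and below; see "Problem sizes" at the end.

The forward and backward passes are written directly in base R matrix
operations (the gradient of every block is verified against central
finite differences in the test suite, and the batched encoder against a
dense arc-by-arc reimplementation). The optimizer is Adam with a linear
warm-up to the peak learning rate followed by exponential decay; batches
are reshuffled every epoch under a seed derived from
`(config seed, epoch)`, so a training run is a pure function of (data,
config).

## Curation and splits

Two filters mirror how continuum-solvation training tables are cleaned:

* `requireBothDirections()` keeps a (reaction, solvent) pair only when
  both the forward and the reverse record are present — matching per
  solvent, the strictest reading.
* `filterOutliers()` removes `|ddG| > g_cut` or `|ddH| > h_cut` with
  *strict* inequality, so a record exactly at the boundary survives.
  Pre-training-style cuts are 40/56 kcal/mol (14 standard deviations at
  the corpus spread of 2.76/3.92); fine-tuning-style cuts are 10/18.
  The filter is idempotent by construction.

Splits group before they sample. A reaction split samples a fraction of
*direction-agnostic reaction keys* and sends every record of a chosen
key — both directions, all solvents — to the test set; a solvent split
does the same per solvent. The key is computed from a canonical
graph invariant (iterated Morgan/Weisfeiler–Lehman refinement over the
unmapped graph, components sorted, the two sides sorted), so it is
unchanged by atom renumbering, SMILES spelling, or direction reversal —
this is what makes forward-in-train/reverse-in-test leakage structurally
impossible rather than merely checked. The remaining records are split
record-level into train and validation (default 20% of the remainder).
Fractional group counts round half-up with a minimum of one group. Folds
are independent seeded redraws (seeds `seed .. seed+k−1`), not a
partition — with grouped test sets of a few percent a partition is not
required, and redraws keep each fold's construction identical.

Subsampling utilities mirror the corpus-building steps:
`coverageSample()` draws `n` records while covering every reaction key
and every solvent at least once whenever that is feasible (it prefers
still-uncovered solvents while walking the reaction keys, then falls
back to plain uniform sampling when `n` is below the number of keys);
`weightedSolventSample()` draws ~25 solvents per reaction without
replacement, weighted by a polarity proxy
(`1 + 2 × heteroatom fraction`, user-overridable per solvent), with a
post-pass swap guaranteeing global solvent coverage. Every sampling and
splitting function is a pure function of (input, parameters, seed).

## Transfer learning and ensembling

`trainModel()` always runs to `maxEpochs` and returns the parameter
snapshot of the epoch with the lowest validation loss (pure best-epoch
selection; no halting heuristic, as only best-epoch selection is
well-defined at the short fine-tuning budgets involved). Passing a
pre-trained bundle as `init` starts all weights from it and freezes the
architecture and normalisation to the bundle's. The intended budgets are
80 epochs for pre-training and 10 for fine-tuning: long enough to learn
the new distribution, short enough not to overwrite the pre-trained
knowledge. `finetuneEpochSweep()` reproduces the curve that justifies
such a budget: fine-tune validation error and holdout error as a
function of the maximum fine-tuning epoch, with the epoch-0 row being
the pre-trained model itself.

`buildEnsemble()` trains `folds × ensembleSize` models, member `(f, i)`
seeded deterministically from `(seed, f, i)` — five folds of five seeds
give the 25-model ensemble used for final predictions.
`ensemblePredict()` reports the per-target mean and the sample standard
deviation across members as a spread estimate (exactly 0 for a single
model). Checkpoints are single JSON documents carrying a fingerprint of
the architecture and schema; loading re-derives the fingerprint and
refuses a mismatch.

## The synthetic generator, and what passing its tests shows

Real training data for this problem are continuum-solvation calculations
that cannot be reproduced at desk scale, so the package ships a
generator that emulates the *structure* of such a corpus:

* **Reactions**: all three radical families are enumerated from small
  H/C/O fragments (≤ 10 heavy atoms) — bimolecular H-abstraction,
  unimolecular 1,n-H migration, radical addition to a double bond — as
  fully atom-mapped, balanced reaction SMILES with the transferred
  hydrogen explicit, both directions emitted. The pool holds 166
  distinct reactions; the generating template is recovered by
  `classifyReactionFamily()` for 100% of them (a generator/classifier
  cross-check in the tests).
* **Solvents**: a fixed pool of 51 templated solvents (water, alkanes,
  alcohols, diols, ethers, nitriles, amides) annotated with a polarity
  proxy (heteroatom fraction: 1.0 for water, 0.0 for alkanes) and an
  H-bond-donor count.
* **Targets**: a transparent closed form,
  `ddG = polarity × Σ_c w_c n_c(r) + h × hbd × n_OH(r) + ε`,
  `ddH = α × ddG_noiseless + offset + ε′`, where `n_c(r)` are *net*
  (formed − broken) bond-change counts. Because the weights act on net
  counts, a reverse reaction's structural term is exactly the negation
  of the forward one — the antisymmetry real data approximately obey —
  while both directions draw fresh noise. Noise is seeded by a stable
  hash of (reaction key, direction, solvent, global seed), so any record
  regenerates bit-identically.

Generator conditions were fixed once, before any model had been trained,
and are documented here as the package's study conditions: noise
`σ = 0.3` kcal/mol; `α = 1.4`, mirroring the typical magnitude ratio of
the enthalpy to the free-energy target in continuum-solvation reaction
data; bond-change weights chosen so the simulated `ddG` spread
(sd ≈ 1.8 kcal/mol over the full cross product) is comparable to a real
radical-reaction corpus (sd ≈ 1.9), which puts the targets safely inside
the pre-training magnitude cuts while leaving a realistic dynamic range.

The surrogate depends only on information visible to the model —
bond-change counts (in the CGR difference blocks) and solvent
composition (in the solvent graph) — so recovery experiments are fair:
the function is representable by the architecture, and failure to learn
it would indicate an implementation defect, not an unlearnable target.
That is also the limit of what passing these tests shows about real
data: the surrogate has none of the conformational, electronic or
many-body structure of real solvation energies, so desk-scale recovery
bounds say nothing about real-corpus accuracy. They validate the
machinery (featurization, gradients, splits, transfer protocol), not the
chemistry.

## Numerical choices

* Gas constant `R = 1.98720425864083e−3` kcal/(mol K); reference
  temperature 298.0 K; the enthalpy estimator uses the 297/298/299 K
  stencil.
* Outlier cuts compare with strict inequality; boundary records are
  kept.
* Group counts in splits round half-up; at least one group is always
  selected; degenerate splits (all groups in test) raise an error.
* Reaction keys hash canonical labels into 31-bit integers; label
  refinement runs min(atom count, 12) rounds. Collisions are
  theoretically possible but not observed across the template pool
  (asserted pairwise in tests).
* All randomness flows through explicit integer seeds; derived seeds
  stay below 2^31. Training uses no hidden global RNG state — the
  caller's RNG is restored after every seeded operation.
* Dropout masks are pre-scaled (inverted dropout) and seeded per
  (epoch, batch); prediction never applies dropout.

## Problem sizes used by the tests and acceptance script

The shipped experiments are sized for a single CPU: surrogate recovery
trains on ~2,000 pairs (70 undirected reactions × 20 solvents, 10%
reaction-split test fraction) with hidden 64 / depth 3 / 50 epochs; the
transfer experiment pre-trains on 60 × 15 pairs (25 epochs, hidden 32)
and fine-tunes on a shifted-parameter corpus (weights ×1.3, stronger
H-bond term, +0.8 kcal/mol enthalpy offset) for up to 10 epochs; split
safety is checked on a 10,000-record corpus (100 reactions × 50
solvents) across 5 reaction folds and 5 solvent folds. These sizes are
the package's chosen desk-scale study conditions.

## Known limitations

* No automatic atom mapping: inputs must arrive mapped, and mapping
  defects are rejected, not repaired.
* No 3D, conformer, or solvent-friction effects; predictions are
  relative (no absolute rate constants).
* The SMILES dialect covers the organic subset plus bracket atoms,
  aromatic lowercase, rings and multi-component sides — sufficient for
  the data this model targets, but not a general cheminformatics parser
  (no isotopes, no stereo bonds beyond parsing them as single bonds).
* The temperature extrapolation degrades outside 250–400 K and warns
  there.
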