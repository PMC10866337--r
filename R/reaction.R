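#' @import methods
NULL

#' MappedReaction: an atom-mapped reaction with a map-index bijection
#'
#' Holds the parsed reactant and product graphs of an atom-mapped reaction
#' SMILES (\code{reactants>>products}), the bijection between the two sides
#' keyed by shared atom-map numbers, a direction tag, and the original text.
#'
#' @slot reactant parsed reactant side (internal molecule representation).
#' @slot product parsed product side.
#' @slot mapPairs integer matrix with columns \code{reactant}, \code{product}
#'   (atom indices) and \code{map} (the shared atom-map number).
#' @slot direction \code{"forward"} or \code{"reverse"}.
#' @slot source the original reaction SMILES text.
#' @export
setClass("MappedReaction",
         representation(reactant = "list", product = "list",
                        mapPairs = "matrix", direction = "character",
                        source = "character"))

setValidity("MappedReaction", function(object) {
  if (!object@direction %in% c("forward", "reverse"))
    return("direction must be 'forward' or 'reverse'")
  mp <- object@mapPairs
  if (ncol(mp) != 3L) return("mapPairs must have 3 columns")
  if (anyDuplicated(mp[, 3L])) return("duplicate atom-map numbers in mapPairs")
  TRUE
})

setMethod("show", "MappedReaction", function(object) {
  cat("MappedReaction (", object@direction, ")\n", sep = "")
  cat("  ", object@source, "\n", sep = "")
  cat("  mapped atoms: ", nrow(object@mapPairs),
      " | reactant components: ", object@reactant$component_count,
      " | product components: ", object@product$component_count, "\n", sep = "")
})

#' @describeIn MappedReaction parsed reactant side
#' @param r a \code{MappedReaction}.
#' @export
reactantGraph <- function(r) r@reactant

#' @describeIn MappedReaction parsed product side
#' @export
productGraph <- function(r) r@product

#' @describeIn MappedReaction direction tag
#' @export
directionTag <- function(r) r@direction

#' @describeIn MappedReaction original reaction SMILES
#' @export
sourceText <- function(r) r@source

#' @describeIn MappedReaction map-pair matrix (reactant index, product index,
#'   map number)
#' @export
mapPairs <- function(r) r@mapPairs

#' Parse an atom-mapped reaction SMILES
#'
#' Parses \code{reactants>>products}, requiring every atom written in the
#' SMILES to carry an atom-map number forming a bijection between the two
#' sides, identical elements within each map pair, and a balanced reaction
#' (identical element and hydrogen counts on both sides, implicit hydrogens
#' included). Hydrogens written explicitly (e.g. a transferred \code{[H:5]})
#' become graph atoms and keep their map numbers; spectator implicit
#' hydrogens stay implicit.
#'
#' @param text reaction SMILES with exactly one \code{>>} separator.
#' @param direction direction tag to record, \code{"forward"} by default.
#' @return a [MappedReaction-class] object.
#' @examples
#' r <- parseMappedReaction("[CH3:1][H:2].[O:3][H:4]>>[CH3:1].[H:2][O:3][H:4]")
#' reactionKey(r) == reactionKey(reverseReaction(r))
#' @export
parseMappedReaction <- function(text, direction = "forward") {
  if (!is.character(text) || length(text) != 1L)
    stopParse("reaction SMILES must be a single string")
  sides <- strsplit(text, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L || grepl(">>.*>>", text))
    stopParse("reaction SMILES must contain exactly one '>>': ", text)
  rmol <- parseSmiles(sides[1])
  pmol <- parseSmiles(sides[2])

  for (side in list(r = rmol, p = pmol)) {
    if (anyNA(side$atoms$map))
      stopMapping("unmapped atom in reaction SMILES: ", text)
    if (anyDuplicated(side$atoms$map))
      stopMapping("duplicate atom-map number in reaction SMILES: ", text)
  }
  if (!setequal(rmol$atoms$map, pmol$atoms$map))
    stopMapping("atom-map numbers do not form a bijection in: ", text)

  maps <- sort(rmol$atoms$map)
  ri <- match(maps, rmol$atoms$map)
  pi <- match(maps, pmol$atoms$map)
  if (any(rmol$atoms$element[ri] != pmol$atoms$element[pi]))
    stopMapping("map pair links different elements in: ", text)

  # balance: heavy-atom element multisets and total H count
  rHeavy <- table(factor(rmol$atoms$element[rmol$atoms$element != "H"]))
  pHeavy <- table(factor(pmol$atoms$element[pmol$atoms$element != "H"]))
  totH <- function(mol) sum(mol$atoms$totalH[mol$atoms$element != "H"]) +
    sum(mol$atoms$element == "H")
  if (!identical(sort(names(rHeavy)), sort(names(pHeavy))) ||
      !all(rHeavy[sort(names(rHeavy))] == pHeavy[sort(names(rHeavy))]) ||
      totH(rmol) != totH(pmol))
    stopBalance("unbalanced reaction (atom counts differ between sides): ", text)

  mp <- cbind(reactant = ri, product = pi, map = maps)
  new("MappedReaction", reactant = rmol, product = pmol, mapPairs = mp,
      direction = direction, source = text)
}

#' Reverse a mapped reaction
#'
#' Swaps the reactant and product sides, flips the direction tag, and inverts
#' the map-pair bijection. Applying it twice reproduces the original graphs.
#'
#' @param r a [MappedReaction-class].
#' @return the reversed [MappedReaction-class].
#' @export
reverseReaction <- function(r) {
  sides <- strsplit(r@source, ">>", fixed = TRUE)[[1]]
  mp <- r@mapPairs[, c(2L, 1L, 3L), drop = FALSE]
  colnames(mp) <- c("reactant", "product", "map")
  new("MappedReaction", reactant = r@product, product = r@reactant,
      mapPairs = mp,
      direction = if (r@direction == "forward") "reverse" else "forward",
      source = paste0(sides[2], ">>", sides[1]))
}

#' Direction-agnostic reaction identifier
#'
#' A deterministic key that is identical for a reaction and its reverse and
#' invariant under atom-map renumbering and atom-order permutation: each side
#' is reduced to a canonical graph signature (atom maps ignored, components
#' sorted), and the two side signatures are joined in sorted order. Used for
#' leakage-safe reaction splits, where forward and reverse copies of one
#' reaction must land on the same side of a split.
#'
#' @param r a [MappedReaction-class].
#' @return a character key.
#' @export
reactionKey <- function(r) {
  s1 <- canonicalSideSignature(r@reactant)
  s2 <- canonicalSideSignature(r@product)
  paste(sort(c(s1, s2)), collapse = ">>")
}

pairLabel <- function(e1, e2) {
  # hydrogen printed last, otherwise alphabetical (C-H, O-H, C-O, ...)
  if (e1 == "H" && e2 != "H") paste0(e2, "-", e1)
  else if (e2 == "H" || e1 <= e2) paste0(e1, "-", e2)
  else paste0(e2, "-", e1)
}

sideBondMap <- function(mol, mapOfAtom) {
  out <- list()
  b <- mol$bonds
  if (nrow(b) == 0L) return(out)
  for (k in seq_len(nrow(b))) {
    m1 <- mapOfAtom[b$i[k]]; m2 <- mapOfAtom[b$j[k]]
    key <- paste(min(m1, m2), max(m1, m2), sep = "_")
    out[[key]] <- b$order[k]
  }
  out
}

#' Bond-change signature of a reaction
#'
#' Compares the bonds between mapped atom pairs on the two sides and reports
#' the multisets of formed bonds, broken bonds, and bond-order changes, each
#' labelled by its element pair (hydrogen last: \code{C-H}, \code{O-H}).
#' The signature of a reverse reaction swaps formed and broken. The rendered
#' form follows the \code{+C-H, -C-H, -C-C} convention: a leading \code{+}
#' marks a formed bond and \code{-} a broken one.
#'
#' @param r a [MappedReaction-class].
#' @return a list of class \code{BondChangeSignature} with elements
#'   \code{formed}, \code{broken} (character vectors of element-pair labels,
#'   with multiplicity) and \code{order_changed} (data.frame with columns
#'   \code{label}, \code{old}, \code{new}).
#' @examples
#' r <- parseMappedReaction("[CH3:1][H:2].[O:3][H:4]>>[CH3:1].[H:2][O:3][H:4]")
#' bondChangeSignature(r)
#' @export
bondChangeSignature <- function(r) {
  rb <- sideBondMap(r@reactant, r@reactant$atoms$map)
  pb <- sideBondMap(r@product, r@product$atoms$map)
  elOfMap <- r@reactant$atoms$element[order(r@reactant$atoms$map)]
  names(elOfMap) <- sort(r@reactant$atoms$map)
  labelOf <- function(key) {
    ms <- strsplit(key, "_")[[1]]
    pairLabel(elOfMap[[ms[1]]], elOfMap[[ms[2]]])
  }
  formed <- character(0); broken <- character(0)
  oc <- data.frame(label = character(0), old = numeric(0), new = numeric(0))
  for (key in union(names(rb), names(pb))) {
    ro <- rb[[key]]; po <- pb[[key]]
    if (is.null(ro) && !is.null(po)) formed <- c(formed, labelOf(key))
    else if (!is.null(ro) && is.null(po)) broken <- c(broken, labelOf(key))
    else if (ro != po)
      oc <- rbind(oc, data.frame(label = labelOf(key), old = ro, new = po))
  }
  structure(list(formed = sort(formed), broken = sort(broken),
                 order_changed = oc[order(oc$label), , drop = FALSE]),
            class = "BondChangeSignature")
}

#' @describeIn bondChangeSignature render a signature as the conventional
#'   comma-separated string (\code{"+O-H, -C-H"}); order changes are rendered
#'   as \code{label:old>new}.
#' @param sig a \code{BondChangeSignature}.
#' @export
formatSignature <- function(sig) {
  parts <- c(if (length(sig$formed)) paste0("+", sig$formed),
             if (length(sig$broken)) paste0("-", sig$broken),
             if (nrow(sig$order_changed))
               paste0(sig$order_changed$label, ":",
                      sig$order_changed$old, ">", sig$order_changed$new))
  paste(parts, collapse = ", ")
}

#' @export
print.BondChangeSignature <- function(x, ...) {
  cat("BondChangeSignature:", formatSignature(x), "\n")
  invisible(x)
}

#' Classify a reaction into a radical-reaction family
#'
#' Template matching on the bond-change signature and molecularity:
#' \itemize{
#'   \item \code{H-abstraction}: bimolecular, exactly one X-H bond broken and
#'     one Y-H bond formed, nothing else changing;
#'   \item \code{H-migration}: the same bond pattern but unimolecular;
#'   \item \code{R-addition}: one new sigma bond plus one bond-order decrease
#'     on a multiple bond (radical addition), or the reverse scission;
#'   \item \code{other}: anything else.
#' }
#' A reverse direction inherits the forward family label, so e.g. the
#' beta-scission reverse of a radical addition is labelled
#' \code{R-addition}.
#'
#' @param r a [MappedReaction-class].
#' @return one of \code{"H-abstraction"}, \code{"H-migration"},
#'   \code{"R-addition"}, \code{"other"}.
#' @export
classifyReactionFamily <- function(r) {
  matchForward <- function(rr) {
    sig <- bondChangeSignature(rr)
    nF <- length(sig$formed); nB <- length(sig$broken)
    nO <- nrow(sig$order_changed)
    rComp <- rr@reactant$component_count
    pComp <- rr@product$component_count
    isH <- function(lab) grepl("-H$", lab) | lab == "H-H"
    if (nF == 1L && nB == 1L && nO == 0L &&
        isH(sig$formed) && isH(sig$broken)) {
      if (rComp == 2L && pComp == 2L) return("H-abstraction")
      if (rComp == 1L && pComp == 1L) return("H-migration")
    }
    if (nF == 1L && nB == 0L && nO == 1L &&
        sig$order_changed$new < sig$order_changed$old &&
        rComp == 2L && pComp == 1L) return("R-addition")
    NA_character_
  }
  fwd <- matchForward(r)
  if (!is.na(fwd)) return(fwd)
  rev <- matchForward(reverseReaction(r))
  if (!is.na(rev)) return(rev)
  "other"
}
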