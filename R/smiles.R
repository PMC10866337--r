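# Minimal SMILES reader for the dialect used by reaction and solvent tables:
# organic-subset atoms, bracket atoms with charge/H-count/atom-map, aromatic
# lowercase, branches, ring closures (incl. %nn), "." for multiple components.
# Atom-map numbers are preserved, which is what distinguishes this reader from
# SDF round-trips that drop them.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)
.ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06, F = 18.998, Cl = 35.45, Br = 79.904,
                  I = 126.904)
.ELECTRONEGATIVITY <- c(H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44,
                        P = 2.19, S = 2.58, F = 3.98, Cl = 3.16, Br = 2.96,
                        I = 2.66)

# Parse one (possibly multi-component) SMILES into atom and bond tables.
# Returns list(atoms = data.frame(element, aromatic, charge, hexplicit, map,
# component), bonds = data.frame(i, j, order, aromatic)); order uses 1.5 for
# aromatic bonds.
parseSmiles <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stopParse("empty or non-character SMILES input")
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)

  el <- character(0); arom <- logical(0); chg <- integer(0)
  hexp <- integer(0); map <- integer(0); comp <- integer(0)
  bi <- integer(0); bj <- integer(0); bord <- numeric(0); barom <- logical(0)

  prev <- NA_integer_          # previous atom index
  pend <- NA_real_             # pending bond order; NA = default
  pendArom <- NA               # pending bond aromatic flag override
  stack <- integer(0)          # branch stack of atom indices
  rings <- list()              # ring closure id -> list(atom, order)
  compId <- 1L
  i <- 1L

  addAtom <- function(e, ar, charge, hn, mp) {
    el <<- c(el, e); arom <<- c(arom, ar); chg <<- c(chg, as.integer(charge))
    hexp <<- c(hexp, as.integer(hn)); map <<- c(map, as.integer(mp))
    comp <<- c(comp, compId)
    length(el)
  }
  addBond <- function(a, b, order, ar) {
    if (a == b) stopParse("self bond in SMILES: ", text)
    bi <<- c(bi, a); bj <<- c(bj, b); bord <<- c(bord, order)
    barom <<- c(barom, ar)
  }
  connect <- function(idx) {
    if (!is.na(prev)) {
      bothArom <- arom[prev] && arom[idx]
      if (is.na(pend)) {
        addBond(prev, idx, if (bothArom) 1.5 else 1, bothArom)
      } else {
        addBond(prev, idx, pend, isTRUE(pendArom))
      }
    }
    prev <<- idx
    pend <<- NA_real_; pendArom <<- NA
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stopParse("unclosed bracket atom in SMILES: ", text)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]*))?([+-][0-9]*|\\+*|-*)?(:([0-9]+))?$",
        body))[[1]]
      if (length(m) == 0L || !nzchar(m[3]))
        stopParse("cannot parse bracket atom [", body, "] in: ", text)
      sym <- m[3]
      isArom <- sym == tolower(sym) && toupper(substr(sym, 1, 1)) %in% names(.DEFAULT_VALENCE)
      e <- if (isArom) {
        paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      } else sym
      if (!e %in% names(.DEFAULT_VALENCE))
        stopParse("unsupported element '", e, "' in: ", text)
      hn <- if (nzchar(m[5])) { if (nzchar(m[6])) as.integer(m[6]) else 1L } else 0L
      chstr <- m[7]
      charge <- if (!nzchar(chstr)) 0L
        else if (grepl("^[+-][0-9]+$", chstr)) as.integer(chstr)
        else if (grepl("^\\++$", chstr)) nchar(chstr)
        else -nchar(chstr)
      mp <- if (nzchar(m[9])) as.integer(m[9]) else NA_integer_
      idx <- addAtom(e, isArom, charge, hn, mp)
      connect(idx)
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pend <- switch(ch, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "/" = 1, "\\" = 1)
      pendArom <- ch == ":"
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stopParse("branch with no preceding atom in: ", text)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stopParse("unmatched ')' in: ", text)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pend <- NA_real_
      compId <- compId + 1L
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) stopParse("truncated %nn ring closure in: ", text)
        rid <- paste(chars[(i + 1L):(i + 2L)], collapse = "")
        i <- i + 3L
      } else {
        rid <- ch
        i <- i + 1L
      }
      if (is.na(prev)) stopParse("ring closure with no atom in: ", text)
      if (is.null(rings[[rid]])) {
        rings[[rid]] <- list(atom = prev, order = pend, arom = pendArom)
        pend <- NA_real_; pendArom <- NA
      } else {
        op <- rings[[rid]]
        ord <- if (!is.na(op$order)) op$order else pend
        bothArom <- arom[op$atom] && arom[prev]
        if (is.na(ord)) ord <- if (bothArom) 1.5 else 1
        addBond(op$atom, prev, ord,
                isTRUE(op$arom) || isTRUE(pendArom) || (is.na(ord) && bothArom) || ord == 1.5)
        rings[[rid]] <- NULL
        pend <- NA_real_; pendArom <- NA
      }
    } else {
      # organic subset, possibly two-character (Cl, Br)
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% .ORGANIC_SUBSET) {
        idx <- addAtom(two, FALSE, 0L, NA_integer_, NA_integer_)
        connect(idx)
        i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        idx <- addAtom(ch, FALSE, 0L, NA_integer_, NA_integer_)
        connect(idx)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        idx <- addAtom(toupper(ch), TRUE, 0L, NA_integer_, NA_integer_)
        connect(idx)
        i <- i + 1L
      } else {
        stopParse("unexpected character '", ch, "' in SMILES: ", text)
      }
    }
  }
  if (length(stack) > 0L) stopParse("unclosed branch in SMILES: ", text)
  if (length(rings) > 0L) stopParse("unclosed ring bond in SMILES: ", text)
  if (length(el) == 0L) stopParse("SMILES contains no atoms: ", text)

  atoms <- data.frame(element = el, aromatic = arom, charge = chg,
                      hexplicit = hexp, map = map, component = comp,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = bi, j = bj, order = bord, aromatic = barom)
  finalizeMol(atoms, bonds, text)
}

# Derived per-atom quantities: implicit/total H, degree, radical electrons,
# ring membership of bonds. Bracket atoms carry exactly their written H count;
# organic-subset atoms get implicit H from default valences.
finalizeMol <- function(atoms, bonds, source) {
  nA <- nrow(atoms)
  bondSum <- numeric(nA)
  degree <- integer(nA)
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      bondSum[bonds$i[k]] <- bondSum[bonds$i[k]] + bonds$order[k]
      bondSum[bonds$j[k]] <- bondSum[bonds$j[k]] + bonds$order[k]
      degree[bonds$i[k]] <- degree[bonds$i[k]] + 1L
      degree[bonds$j[k]] <- degree[bonds$j[k]] + 1L
    }
  }
  valence <- .DEFAULT_VALENCE[atoms$element] + atoms$charge
  valence <- pmax(valence, 0)
  bracket <- !is.na(atoms$hexplicit)
  implicitH <- integer(nA)
  idx <- which(!bracket)
  if (length(idx))
    implicitH[idx] <- pmax(0L, as.integer(valence[idx] - ceiling(bondSum[idx])))
  totalH <- ifelse(bracket, atoms$hexplicit, implicitH)
  radicals <- pmax(0L, as.integer(round(valence - ceiling(bondSum) - totalH)))
  # H written as its own bracket atom has no radical electron
  radicals[atoms$element == "H" & degree > 0L] <- 0L

  inRing <- ringBonds(nA, bonds)
  atoms$implicitH <- implicitH
  atoms$totalH <- as.integer(totalH)
  atoms$degree <- degree
  atoms$radicals <- radicals
  bonds$inRing <- inRing
  list(atoms = atoms, bonds = bonds, source = source,
       component_count = length(unique(atoms$component)))
}

# A bond is in a ring iff its endpoints stay connected after removing it.
ringBonds <- function(nA, bonds) {
  nB <- nrow(bonds)
  if (nB == 0L) return(logical(0))
  out <- logical(nB)
  adj <- vector("list", nA)
  for (k in seq_len(nB)) {
    adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], k)
    adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], k)
  }
  for (k in seq_len(nB)) {
    start <- bonds$i[k]; goal <- bonds$j[k]
    seen <- logical(nA); seen[start] <- TRUE
    queue <- start
    found <- FALSE
    while (length(queue) && !found) {
      a <- queue[1]; queue <- queue[-1]
      for (kk in adj[[a]]) {
        if (kk == k) next
        b <- if (bonds$i[kk] == a) bonds$j[kk] else bonds$i[kk]
        if (b == goal) { found <- TRUE; break }
        if (!seen[b]) { seen[b] <- TRUE; queue <- c(queue, b) }
      }
    }
    out[k] <- found
  }
  out
}

# Canonical isomorphism-invariant label per atom via iterated neighbourhood
# refinement (Morgan/Weisfeiler-Lehman style); atom maps are ignored so the
# result is stable under renumbering. Labels are 31-bit integer hashes that
# are comparable across molecules.
canonicalAtomLabels <- function(mol) {
  atoms <- mol$atoms; bonds <- mol$bonds
  nA <- nrow(atoms)
  lab <- vapply(seq_len(nA), function(a) {
    stableHash(paste(atoms$element[a], atoms$aromatic[a], atoms$charge[a],
                     atoms$totalH[a], atoms$radicals[a], sep = "|"))
  }, integer(1))
  if (nrow(bonds) == 0L || nA == 1L) return(lab)
  nbr <- vector("list", nA)
  for (k in seq_len(nrow(bonds))) {
    nbr[[bonds$i[k]]] <- rbind(nbr[[bonds$i[k]]], c(bonds$j[k], bonds$order[k]))
    nbr[[bonds$j[k]]] <- rbind(nbr[[bonds$j[k]]], c(bonds$i[k], bonds$order[k]))
  }
  for (iter in seq_len(min(nA, 12L))) {
    lab <- vapply(seq_len(nA), function(a) {
      nb <- nbr[[a]]
      parts <- sort(paste0(nb[, 2], ":", lab[nb[, 1]]))
      stableHash(paste(lab[a], paste(parts, collapse = ","), sep = ";"))
    }, integer(1))
  }
  lab
}

# Canonical signature of one molecule (order-invariant): sorted multiset of
# final atom labels plus a global bond summary.
canonicalMolSignature <- function(mol) {
  lab <- canonicalAtomLabels(mol)
  bondPart <- if (nrow(mol$bonds) > 0L) {
    bl <- sort(paste0(pmin(lab[mol$bonds$i], lab[mol$bonds$j]), "~",
                      pmax(lab[mol$bonds$i], lab[mol$bonds$j]), "~",
                      mol$bonds$order))
    paste(bl, collapse = "+")
  } else ""
  paste0(paste(sort(lab), collapse = ","), "|", stableHash(bondPart))
}

# Signature for a multi-component side: sorted component signatures.
canonicalSideSignature <- function(mol) {
  comps <- sort(unique(mol$atoms$component))
  sigs <- vapply(comps, function(cc) {
    keep <- which(mol$atoms$component == cc)
    remap <- match(seq_len(nrow(mol$atoms)), keep)
    sub <- list(
      atoms = mol$atoms[keep, , drop = FALSE],
      bonds = {
        b <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, , drop = FALSE]
        b$i <- remap[b$i]; b$j <- remap[b$j]
        b
      })
    canonicalMolSignature(sub)
  }, character(1))
  paste(sort(sigs), collapse = ".")
}
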