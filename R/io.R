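# Reaction-solvent property table I/O. Dataset files are UTF-8 CSV with a
# header row and one record per reaction-solvent pair.

.REQUIRED_COLS <- c("rxn_smiles", "solvent_smiles", "ddG_298", "ddH_298")
.OPTIONAL_COLS <- c("direction", "reaction_key", "provenance", "family")

#' Read a reaction-solvent pair table
#'
#' Expects a CSV with header columns \code{rxn_smiles}, \code{solvent_smiles},
#' \code{ddG_298}, \code{ddH_298} (kcal/mol at 298 K); any further columns
#' beyond the known optional ones (\code{direction}, \code{reaction_key},
#' \code{provenance}, \code{family}) are treated as molecular extras (e.g.
#' the four reactant/product solvation columns \code{dGsolv_R, dHsolv_R,
#' dGsolv_P, dHsolv_P}) and recorded in the returned table's
#' \code{"extrasCols"} attribute. Column spellings can be remapped via
#' \code{schema}.
#'
#' In strict mode (default) any row with a non-finite target or unparsable
#' reaction aborts with the offending line numbers; in permissive mode such
#' rows are dropped (never repaired) and reported via the
#' \code{"rejected"} attribute.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping file column names
#'   to the canonical names, e.g. \code{c(rxn = "rxn_smiles")}.
#' @param permissive drop bad rows instead of failing.
#' @param validate parse every distinct reaction SMILES (slower; catches
#'   mapping/balance defects at load time).
#' @return a pair-record data.frame with attributes \code{extrasCols} and,
#'   in permissive mode, \code{rejected} (data.frame of line numbers and
#'   reasons).
#' @export
readPairTable <- function(path, schema = NULL, permissive = FALSE,
                          validate = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, encoding = "UTF-8")
  if (!is.null(schema)) {
    hit <- match(names(schema), names(df))
    names(df)[hit[!is.na(hit)]] <- unname(schema[!is.na(hit)])
  }
  missing <- setdiff(.REQUIRED_COLS, names(df))
  if (length(missing))
    stopSchema("pair table lacks required column(s): ",
               paste(missing, collapse = ", "))
  extras <- setdiff(names(df), c(.REQUIRED_COLS, .OPTIONAL_COLS))
  rejected <- data.frame(line = integer(0), reason = character(0))
  bad <- !is.finite(df$ddG_298) | !is.finite(df$ddH_298)
  if (validate && nrow(df)) {
    rxnU <- unique(df$rxn_smiles)
    ok <- vapply(rxnU, function(s) {
      !inherits(tryCatch(parseMappedReaction(s), error = identity), "error")
    }, logical(1))
    bad <- bad | !ok[match(df$rxn_smiles, rxnU)]
  }
  if (any(bad)) {
    lines <- which(bad) + 1L   # +1 for the header row
    if (!permissive)
      stopSchema("invalid row(s) at line(s): ",
                 paste(utils::head(lines, 20L), collapse = ", "))
    rejected <- data.frame(line = lines,
                           reason = "non-finite target or unparsable reaction")
    df <- df[!bad, , drop = FALSE]
  }
  for (col in extras) {
    if (!is.numeric(df[[col]]))
      stopSchema("extras column '", col, "' is not numeric")
  }
  rownames(df) <- NULL
  attr(df, "extrasCols") <- extras
  attr(df, "rejected") <- rejected
  df
}

#' @rdname readPairTable
#' @param records a pair-record data.frame.
#' @return \code{writePairTable} returns \code{path} invisibly; numeric
#'   columns are written with full precision so a write-read round trip is
#'   lossless.
#' @export
writePairTable <- function(records, path) {
  out <- records
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
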