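# Internal helpers: condition constructors and seeded RNG scoping.

kinsolvError <- function(class, message, ...) {
  structure(
    class = c(class, "kinsolvError", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

stopParse   <- function(msg, ...) stop(kinsolvError("ParseError", msg, ...))
stopMapping <- function(msg, ...) stop(kinsolvError("MappingError", msg, ...))
stopBalance <- function(msg, ...) stop(kinsolvError("BalanceError", msg, ...))
stopSchema  <- function(msg, ...) stop(kinsolvError("SchemaError", msg, ...))
stopFeature <- function(msg, ...) stop(kinsolvError("FeatureError", msg, ...))
stopShape   <- function(msg, ...) stop(kinsolvError("ShapeError", msg, ...))
stopUsage   <- function(msg, ...) stop(kinsolvError("UsageError", msg, ...))

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  force(expr)
}

# Stable 31-bit integer hash of a character string (FNV-1a folded), used to
# derive per-record noise seeds that are reproducible across sessions.
stableHash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; keep h in double range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619, kept exact in double
    # by splitting h into 16-bit halves
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# Derive a child seed from a parent seed and one or more integer indices.
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (i in idx) h <- (h * 48271 + as.double(i) + 1) %% 2147483647
  as.integer(h)
}
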