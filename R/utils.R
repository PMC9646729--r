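# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; if seed is NULL
# the expression uses (and advances) the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' Stable arithmetic derivation so every pipeline stage (and every replicate
#' within a stage) gets its own reproducible stream while the whole run is
#' controlled by one master seed. Values stay below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage stage index or name (names are hashed by character codes).
#' @param index replicate index within the stage (default 0).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, stage, index = 0) {
  if (is.character(stage)) {
    stage <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  }
  m <- 2147483646 # 2^31 - 2
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(stage) * 1000003 +
    as.numeric(index) * 7919
  as.integer(s %% m + 1)
}

# Split a residue string into single characters.
seq_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1]] else as.character(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
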