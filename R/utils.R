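# Internal helpers shared across modules.

#' Run an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' disturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a parent seed (kept < 2^31).
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 7919L + as.integer(offset) * 104729L) %% 2147483587L
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# Polynomial rolling hash over a serialized object; provenance only (not
# cryptographic). Deterministic across sessions for identical configs.
config_hash <- function(x) {
  raw <- as.integer(serialize(x, connection = NULL, version = 2))
  m <- 2147483629
  h <- 0
  # process in chunks so the loop stays short for large objects
  for (chunk in split(raw, ceiling(seq_along(raw) / 512))) {
    for (b in chunk) h <- (h * 131 + b) %% m
  }
  sprintf("%08x", as.integer(h))
}
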