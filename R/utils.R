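# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means "use the ambient RNG stream" (no save/restore).
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministically derive n sub-seeds from a root seed, so individual
# stages can be re-run in isolation. Values stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(rep(list(NULL), n))
  }
  as.list(with_seed(seed, sample.int(2147483646L, n, replace = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
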