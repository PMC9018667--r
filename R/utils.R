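# Internal helpers shared across modules.

# Deterministically derive a child seed from (seed, k); result in [1, 2^31-2]
# so it is always a valid 32-bit integer seed.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(k) * 16807 + 1
  as.integer(s %% 2147483646) + 1L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
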