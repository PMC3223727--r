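# Internal helpers: scoped RNG, tiny hashing, assertions.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used to fingerprint configurations in run logs; not cryptographic.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h a double since it
    # exceeds R's 32-bit signed integers
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime, in 16-bit limbs to stay
    # within exact double-precision integers
    h0 <- h %% 65536; h1 <- h %/% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  # h is a double (possibly > .Machine$integer.max); print in halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
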