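# internal helpers

# Evaluate expr under a transient RNG seed; NULL keeps the caller's stream.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

asSeed <- function(seed) {
  if (is.null(seed)) NA_integer_ else as.integer(seed)
}

stopIf <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}
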