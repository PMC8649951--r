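# Small shared helpers.

t1moco_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "t1moco_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Evaluate `code` under a local RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a base seed and stream labels, keeping the result
# a valid 32-bit integer.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1000003 + as.numeric(p)) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
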