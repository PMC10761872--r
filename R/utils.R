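# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stage offset,
# keeping the result inside the 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) * 1103L + offset * 7919L) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Benjamini-Hochberg with NA p-values excluded from the denominator
# (non-convergent fits must not inflate m).
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}
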