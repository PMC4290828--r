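# Internal helpers.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards. All stochastic operations in the package route through
# this so that a master seed makes every sub-computation reproducible in
# isolation.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based derivation of per-task seeds from a master seed, kept inside
# 32-bit integer range.
deriveSeed <- function(master, counter) {
  as.integer((as.numeric(master) * 7919 + as.numeric(counter) * 104729) %%
               2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
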