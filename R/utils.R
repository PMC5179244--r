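# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic operations in the package
# route through this so that results are reproducible from explicit seeds.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed. Keeps values
# within 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12345L) %% 2147483647)
}

# Integer tenth-degree representation of a coordinate; tol absorbs the
# floating-point representation error of decimal degrees (~1e-9 deg).
to_tenths <- function(x) floor(x * 10 + 1e-9)
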