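# Internal helpers shared across modules.

# Population (1/n) standard deviation.  Used for every sigma in the package
# (activation SD sigma_S, noise SD sigma_N, temporal SD in tSNR maps) so that
# ratios of the two are internally consistent; at the series lengths used
# here (n >= 100) the difference from the n-1 convention is below 0.5%.
sdPop <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  seed = NULL runs unseeded.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible 31-bit sub-seed from a base seed and a stream index,
# so that each grid cell of a simulation is reproducible in isolation.
subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %%
               2147483647)
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}
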