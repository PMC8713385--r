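# Internal helpers: seeded evaluation and argument checks.

# Evaluate `expr` under a temporary RNG state.  Restores the caller's
# .Random.seed afterwards so library code never clobbers user RNG streams.
# seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Deterministically spawn `n` sub-seeds from one master seed.  Kept below
# 2^31 so they are valid R integer seeds.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar01 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1)
    stop(sprintf("`%s` must be a single number strictly between 0 and 1", name),
         call. = FALSE)
  invisible(x)
}

is_binary <- function(x) all(x %in% c(0, 1))

`%||%` <- function(a, b) if (is.null(a)) b else a
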