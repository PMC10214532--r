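# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user
# simulations.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic stream of child seeds from a base seed; kept strictly below
# 2^31 so they are valid R integers.
derive_seed <- function(seed, k) {
  v <- ((as.double(seed) %% 2147483647) * 48271 + 104729 * as.double(k))
  as.integer(v %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Memoize a function returning list(value, gradient) so optim's separate
# fn/gr calls at the same theta cost one evaluation.
memo_objective <- function(core) {
  last_th <- NULL
  last <- NULL
  get1 <- function(th) {
    if (is.null(last_th) || !identical(th, last_th)) {
      last <<- core(th)
      last_th <<- th
    }
    last
  }
  list(fn = function(th) get1(th)$value,
       gr = function(th) get1(th)$gradient)
}
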