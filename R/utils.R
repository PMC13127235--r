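#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic operations in the package
# route through this so that identical configs give bit-identical output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed; keeps results < 2^31.
child_seed <- function(seed, k) {
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The standard logistic; used by the Beck double-logistic model throughout.
logistic <- function(x) stats::plogis(x)

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
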