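# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Scalar checks used by configuration validators; `name` feeds the error.
check_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_min && x <= min) stopf("'%s' must be > %g", name, min)
  if (!strict_min && x < min) stopf("'%s' must be >= %g", name, min)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, min = min)
  if (x != as.integer(x)) stopf("'%s' must be an integer", name)
  invisible(as.integer(x))
}

# Effective library sizes: column sums scaled by TMM factors.
effective_lib_sizes <- function(counts, factors) {
  lib <- colSums(counts)
  f <- factors$factors[colnames(counts)]
  if (anyNA(f)) stopf("normalization factors missing for some samples")
  lib * f
}
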