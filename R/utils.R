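# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls do not perturb user simulations.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_if_not_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite entries", name), call. = FALSE)
  invisible(x)
}

is_binary <- function(x) all(x %in% c(0, 1))

# Numerically safe log for cross-entropy terms: decoder outputs are clamped
# away from exact 0/1 before taking logs.
.log_clamp <- function(x, eps = 1e-10) log(pmin(pmax(x, eps), 1 - eps))
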