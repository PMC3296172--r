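# Internal helpers shared across modules.

bd_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "barcodelim_error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so seeded simulation code does
#' not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded child seed from a base seed (kept below .Machine$integer.max).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset)) %% 2147483629L)
}
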