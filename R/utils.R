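# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package funnel through this so that every
# public function taking a `seed` argument is bit-reproducible.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Multiplicative inverse of u modulo G (u must be a unit).
mod_inv <- function(u, G) {
  for (v in seq_len(G - 1L)) if ((u * v) %% G == 1L) return(v)
  stop("`u` = ", u, " is not invertible modulo ", G)
}

mod_units <- function(G) {
  us <- seq_len(G - 1L)
  us[vapply(us, function(u) {
    r <- u; g <- G
    while (g != 0L) { tmp <- r %% g; r <- g; g <- tmp }
    r == 1L
  }, logical(1))]
}

stopifnot_scalar_int <- function(x, name, min = NULL) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x))
    stop("`", name, "` must be a single integer")
  if (!is.null(min) && x < min)
    stop("`", name, "` must be >= ", min)
  invisible(as.integer(x))
}
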