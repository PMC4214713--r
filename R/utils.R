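# Internal helpers: argument checks and seeded substreams.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_input("`", name, "` must be a single positive finite number")
  as.numeric(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop_input("`", name, "` must be a single integer >= ", min)
  as.integer(x)
}

check_matrix_finite <- function(X, name) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X)) stop_input("`", name, "` must be numeric")
  if (length(X) && !all(is.finite(X)))
    stop_input("`", name, "` contains non-finite entries")
  storage.mode(X) <- "double"
  X
}

# Deterministic substream seed derived from a study seed and a sequence of
# keys (integers or labels). Mixing is a 31-bit multiplicative hash; keeps
# the result a valid 32-bit seed for set.seed().
derive_seed <- function(seed, ...) {
  m <- 2147483647
  x <- as.double(seed %% m)
  for (k in list(...)) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    x <- (x * 48271 + as.double(k) + 1) %% m
  }
  as.integer(x)
}

# Evaluate `expr` under a dedicated RNG substream, restoring the caller's
# RNG state afterwards so independent substreams never interleave.
with_substream <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
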