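# Seed derivation and scoped RNG use.
#
# One master seed drives every stochastic component (partitioning, learner
# fits, tie-breaks) through independently derived sub-seeds, so each
# component is reproducible in isolation and adding a component does not
# shift the stream of another.

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Hashes the master seed together with an arbitrary sequence of labels
#' (model ids, repeat/fold indices, stream names) into an integer seed in
#' `[0, 2^31 - 2]`.  The same `(seed, ...)` always yields the same sub-seed.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(1, "folds", 3)
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
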