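# Small shared utilities.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the given seed, evaluates `expr`, and restores the caller's RNG
#' state afterwards, so seeded helpers do not disturb the surrounding
#' random stream.  With `seed = NULL` the expression simply uses the
#' current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a bounded child seed from a root seed and a stream label, so all
# randomness in a pipeline flows from one root seed.  Kept below 2^31.
derive_seed <- function(root, stream) {
  root <- as.integer(root)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(root) * 48271 + h) %% 2147483399) + 1L
}
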