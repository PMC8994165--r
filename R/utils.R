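# Internal helpers: seeded RNG streams and small numeric utilities.

#' Create an isolated RNG stream
#'
#' Returns an environment holding its own `.Random.seed` state so that draws
#' from the stream never disturb (and are never disturbed by) the global RNG.
#' Used by the simulated machine and the test scheduler so that responses and
#' presentation order are reproducible independently of each other.
#'
#' @param seed integer seed.
#' @return an environment of class `rng_stream`.
#' @keywords internal
#' @noRd
rng_stream <- function(seed) {
  stream <- new.env(parent = emptyenv())
  stream$seed <- as.integer(seed)
  stream$state <- NULL
  class(stream) <- "rng_stream"
  stream
}

# Evaluate `expr` with the stream's RNG state installed, then put the global
# state back exactly as it was.
with_stream <- function(stream, expr) {
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  if (is.null(stream$state)) {
    set.seed(stream$seed)
  } else {
    assign(".Random.seed", stream$state, envir = genv)
  }
  on.exit({
    stream$state <- get(".Random.seed", envir = genv, inherits = FALSE)
    if (had_seed) assign(".Random.seed", old, envir = genv)
    else rm(".Random.seed", envir = genv)
  })
  expr
}

# Run expr under a temporary global seed, restoring the previous RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  set.seed(seed)
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = genv)
    else rm(".Random.seed", envir = genv)
  })
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_perisim <- function(..., class = "perisim_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
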