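#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded helpers do not disturb
#' the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' Counter-based derivation so pipeline stages can be rerun independently:
#' \code{stage_seed = (seed * 48271 + 1000003 * index) mod (2^31 - 1)}.
#' \code{index} is the stage's fixed position in the pipeline (or any
#' documented counter).
#'
#' @param seed Global integer seed.
#' @param index Non-negative stage counter.
#' @return An integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + 1000003 * as.numeric(index)
  as.integer(s %% m + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

relative_err <- function(a, b) {
  d <- max(abs(a - b))
  s <- max(abs(b))
  if (s == 0) d else d / s
}
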