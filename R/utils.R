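#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' seeded package internals never disturb the user's random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-item substream seed from a global seed
#'
#' Deterministic mixing of (seed, id) into a 31-bit seed, so per-frame
#' noise streams do not depend on generation order.
#' @keywords internal
derive_seed <- function(seed, id) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (k in c(as.double(id) + 1, 97)) {
    s <- (s * 48271 + k * 16807) %% 2147483647
  }
  as.integer(s)
}
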