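#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages of the pipeline (droplet placement, filament
#' growth, partitioning noise, camera noise) draw their randomness from a
#' single master seed through this function, so that a run is fully
#' reproducible while the stages remain statistically independent. The
#' derivation is a fixed integer hash of `(seed, stream)`; results are
#' always in `[1, 2^31 - 2]`.
#'
#' @param seed Master integer seed.
#' @param stream Integer stream index (e.g. a droplet id or frame index),
#'   or a character label which is hashed by its character codes.
#' @return An integer seed suitable for [set.seed()].
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, "noise")
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  stopifnot(is.numeric(stream), length(stream) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  # two rounds of multiplicative mixing in double precision (exact below 2^53)
  h <- (abs(seed) %% m) + 1
  h <- (h * 48271) %% m
  h <- (h + (abs(stream) %% m) * 16807) %% m
  h <- (h * 69621) %% m
  as.integer(h + 1)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the previous global RNG
#' state so library code never perturbs the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
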