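## Run code under a fixed seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a named substream seed from a master seed
#'
#' Stages of the pipeline (ensemble, trials, split, classifier, ...) draw
#' their randomness from independent substreams so each stage can be
#' re-run with identical randomness. The derivation is a small
#' deterministic hash of the stream name folded into the master seed,
#' kept below 2^31.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @return integer seed.
#' @export
derive_seed <- function(master, stream) {
  m <- 2147483647
  s <- as.numeric(master) %% m
  ## all intermediates stay below 2^53, so the arithmetic is exact
  for (ch in utf8ToInt(stream)) s <- (s * 131 + ch) %% m
  s <- (s * 48271) %% m
  s <- (s * 48271) %% m
  as.integer(s)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
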