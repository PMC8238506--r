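# Deterministic per-operation stream derivation from a master seed, so that
# reproducibility does not depend on the order in which generators are called.

#' Derive an operation-specific RNG seed
#'
#' Maps a master seed and an operation label to a 31-bit seed via a
#' polynomial string hash.  Different labels give independent-looking
#' streams; the same `(seed, label)` pair always gives the same stream.
#'
#' @param seed Master seed (integer).
#' @param label Operation label (character scalar).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(label) == 1L, is.character(label))
  M <- 2147483647
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% M
  as.integer((h + (as.numeric(seed) %% M) * 2654435) %% M)
}

# Run `expr` under the derived stream without disturbing the caller's RNG.
with_stream <- function(seed, label, expr) {
  withr::with_seed(derive_seed(seed, label), expr)
}
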