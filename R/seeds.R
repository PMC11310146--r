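#' Derive a named substream seed from a master seed
#'
#' Every stochastic stage of the pipeline (landscape synthesis, track
#' simulation, available-point sampling, cross-validation folds,
#' bootstrapping) draws its seed deterministically from one master seed and a
#' stage name, so whole runs are reproducible from a single integer while the
#' stages stay statistically decoupled.
#'
#' @param seed Master seed (integer).
#' @param stream Stage name, e.g. `"landscape"`, `"track"`, `"sampling"`,
#'   `"bootstrap"`.
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(stream)) {
    # 31-based polynomial rolling hash, kept in double-safe range
    h <- (h * 31 + ch) %% m
  }
  as.integer((h * 48271) %% m)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  force(expr)
}
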