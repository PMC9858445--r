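#' Derive a named substream seed from a run seed
#'
#' All randomness in the package flows from a single run seed through named
#' substreams ("split", "balance", "init", "support", ...) so that every
#' stage is independently reproducible and stages do not perturb each
#' other's draws.
#'
#' @param seed Integer run seed.
#' @param name Character substream name; distinct names give (with
#'   overwhelming probability) distinct streams.
#' @return An integer seed suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1L, "split")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  # polynomial string hash kept below sqrt(2^53) so products stay exact
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% 94906249
  s <- abs(as.numeric(seed)) %% 94906249
  as.integer((h * 7919 + s * 104729 + 1) %% 2147483629)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}
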