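#' Derive a reproducible substream seed
#'
#' Mixes a master seed with one or more integer indices (realization number,
#' patient index, ...) into a single seed below 2^31. Streams derived for
#' distinct index tuples are decoupled in practice, and a given tuple always
#' maps to the same seed, so per-patient event streams are common random
#' numbers across runs that share a master seed.
#'
#' @param master Master seed (non-negative integer).
#' @param ... Integer indices identifying the substream.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 3, 117)
derive_seed <- function(master, ...) {
  idx <- c(...)
  stopifnot(is.numeric(master), length(master) == 1, master >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  h <- (master %% m)
  for (x in c(idx, 0)) {
    # two LCG rounds per index; all products < 2^53 so double arithmetic is exact
    h <- (h * 69069 + (x %% m) + 1) %% m
    h <- (h * 48271 + 11) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded helpers do not disturb the
#' caller's RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}
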