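#' Derive a reproducible child seed
#'
#' Deterministically folds one or more integer indices into a parent seed so
#' that independent stages (per-sample rendering, per-run model fits, fold
#' assignment, ...) draw from unrelated but reproducible streams. The map is a
#' multiply-add hash modulo the Mersenne prime 2^31 - 1, so results always fit
#' in a 32-bit R integer and are never zero.
#'
#' @param seed parent seed (single integer).
#' @param ... one or more non-negative integer indices.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @examples
#' child_seed(42, 1)
#' child_seed(42, 1, 3)  # different stream
#' @export
child_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(seed) == 1L, is.finite(seed), length(idx) >= 1L)
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (k in idx) {
    # 1000003 * (m - 1) < 2^53: exact in double arithmetic
    h <- (h * 1000003 + as.numeric(k) + 1) %% m
  }
  as.integer(h + 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
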