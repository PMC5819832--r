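#' Derive a reproducible sub-seed from a root seed
#'
#' All stochastic operations in the package take an explicit seed; nested
#' operations (e.g. one seed per simulation replicate) derive sub-seeds with
#' this mixing function so that replicate `k` is reproducible in isolation
#' and different replicates use effectively independent streams.
#'
#' @param root integer root seed.
#' @param ... further integer indices (replicate number, stage index, ...).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, 2, 7)
#' @export
derive_seed <- function(root, ...) {
  idx <- c(...)
  stopifnot(is.numeric(root), length(root) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; doubles are exact below 2^53
  h <- (abs(root) %% m)
  for (i in idx) {
    h <- (h * 69069 + (abs(i) %% m) + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Run `expr` under `set.seed(seed)` and restore the caller's RNG state, so
# package internals never disturb user-level reproducibility.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Abort with a classed condition so callers can test error categories.
hid_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "hid_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
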