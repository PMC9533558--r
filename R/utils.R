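# Internal helpers shared across modules.

#' Derive a deterministic substream seed from a root seed and a key
#'
#' All randomness in the package flows from one root seed; named substreams
#' keep fixtures reproducible even when stages are added or reordered.
#' The result is always a valid 32-bit integer seed.
#'
#' @param root integer root seed
#' @param key character substream label
#' @return an integer seed in [0, 2^31 - 2]
#' @keywords internal
substream_seed <- function(root, key) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  h <- 0
  # hash the root into the stream so that nearby roots do not yield
  # shifted copies of each other's substreams
  for (ch in utf8ToInt(paste0(format(root), "/", key)))
    h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a seeded, isolated RNG state
#'
#' Restores the caller's `.Random.seed` afterwards so that generators are
#' pure functions of their (config, seed) arguments.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_substream <- function(seed, expr) {
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

# Weighted mean with normalized weights; no NA handling by design --
# exclusions are an explicit pipeline stage, not a silent default.
wmean <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  sum(x * w) / sum(w)
}

# Row-wise product of (1 - h) on the log scale, numerically safe for small h.
surv_from_hazards <- function(h) {
  exp(rowSums(log1p(-h)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
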