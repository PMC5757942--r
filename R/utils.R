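# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# p-values are clipped into [floor, 1] before any log is taken
clip_pvalues <- function(p, floor = 1e-30) {
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p))) {
    stop("p-values must be finite and non-missing", call. = FALSE)
  }
  pmin(pmax(p, floor), 1)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("pleiomap_invalid_argument", "error")))
}

stop_fragmented <- function(epsilon) {
  stop(errorCondition(
    sprintf("fragmented data: the epsilon-neighborhood graph is disconnected at epsilon = %g; increase epsilon (or use auto_epsilon())", epsilon),
    class = c("pleiomap_fragmented_data", "error")
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
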