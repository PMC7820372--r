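# Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  force(code)
}

# Stratified k-fold assignment: returns an integer vector of fold ids (1..k),
# one per sample, with each class spread as evenly as possible across folds.
stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_apofam <- function(...) stop(..., call. = FALSE)
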