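# Internal helpers shared across modules.

# Derive a reproducible 31-bit sub-seed from a master seed and a named
# stream, so that every stage of the pipeline draws from its own stream.
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  val <- (abs(seed) %% 1000003) * 1999 + h * 131 + index * 7919
  as.integer(val %% 2147483647L)
}

# Evaluate `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stratified k-fold assignment: returns an integer fold id per observation,
# with class proportions preserved fold-wise. Shuffle order depends only on
# the current RNG state.
stratified_folds <- function(y, k) {
  y <- as.character(y)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop("class '", cls, "' has ", length(idx), " trials; need at least ",
           k, " for ", k, "-fold cross-validation")
    }
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
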