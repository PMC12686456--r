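# Internal helpers: seeded RNG scoping, seed derivation, rounding.

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate expr under a fixed seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

# Mix a base seed with stream tags into a reproducible 31-bit seed.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 69069 + as.double(t) + 1) %% 2147483647
  as.integer(h)
}

# Round half away from zero to `digits` decimals (the tabular convention
# for percentage indices).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `k` folds so that class proportions are
#' preserved as closely as integer arithmetic allows. Deterministic under
#' `seed`.
#'
#' @param y 0/1 label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  if (k < 2) stop("k must be >= 2")
  if (min(table(y)) < k) stop("a class has fewer members than folds")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
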