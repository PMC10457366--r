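# internal helpers shared across modules

# run expr with a private, seeded RNG stream; the caller's .Random.seed is
# untouched (library code must not consume global random state)
with_private_rng <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_finite_matrix <- function(x, name = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("%s must be a numeric matrix", name)
  if (any(!is.finite(x)))
    stopf("%s contains non-finite values", name)
  invisible(x)
}

# pairwise Euclidean distances between rows of a and rows of b
cross_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
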