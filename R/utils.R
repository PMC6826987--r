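# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps package functions reproducible without
# clobbering the user's random numbers.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from a master seed; keeps every derived seed a
# valid 32-bit integer.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

clamp01 <- function(x) {
  d <- dim(x)
  out <- pmin(1, pmax(0, x))
  dim(out) <- d
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# squared Euclidean distances between rows of X (N x d) and rows of B (C x d)
dist2_matrix <- function(X, B) {
  X <- as.matrix(X)
  B <- matrix(B, ncol = ncol(X))
  N <- nrow(X)
  C <- nrow(B)
  D2 <- matrix(0, N, C)
  for (i in seq_len(C)) {
    diff <- X - matrix(B[i, ], N, ncol(X), byrow = TRUE)
    D2[, i] <- rowSums(diff * diff)
  }
  D2
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}
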