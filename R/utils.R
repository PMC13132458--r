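# Internal numeric and RNG helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded library internals
#' never perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Derive a child seed from a parent seed and integer offsets
#'
#' Deterministic mixing keeps every derived seed below 2^31, so stage seeds
#' can be spawned safely from one global seed.
#'
#' @param seed parent seed.
#' @param ... integer offsets identifying the consumer.
#' @return integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + (as.numeric(p) %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

# Stable 31-bit polynomial rolling hash of a character string.
hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(0L)
  codes <- utf8ToInt(x)
  h <- 7
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer(h)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-wise layer normalization without affine parameters.
# Population variance (1/p) and eps = 1e-5; an all-zero row maps to zero.
layernorm_rows <- function(X, eps = 1e-5) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  Xc / sqrt(v + eps)
}

#' Cosine similarity between two vectors
#'
#' Defined as 0 when either vector is all zeros.
#'
#' @param a,b numeric vectors.
#' @return cosine similarity in \[-1, 1\].
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

is_finite_matrix <- function(X) is.matrix(X) && all(is.finite(X))

#' Null-coalescing operator
#'
#' @param a,b values; returns `b` when `a` is `NULL`.
#' @name op-null-default
#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a
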