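# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Deterministically expands one master seed into per-stream seeds (one per
#' subject, per stage, ...) so that independent stages never share an RNG
#' stream.  Uses a multiplicative congruential step modulo 2^31 - 1; results
#' always fit in a 32-bit integer.
#'
#' @param master integer master seed.
#' @param stream integer stream index (>= 1).
#' @return a single integer seed.
#' @export
child_seed <- function(master, stream) {
  stopifnot(length(master) == 1L, length(stream) == 1L, stream >= 1)
  m <- 2147483647            # 2^31 - 1 (prime)
  a <- 48271                 # MINSTD multiplier
  x <- (as.numeric(master) %% m) + 1
  for (i in seq_len(stream)) x <- (a * x) %% m
  as.integer(x)
}

# Evaluate expr with a local RNG state seeded at `seed`; restores the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Random matrix with orthonormal, column-centred columns: columns are an
# orthonormal basis of a random k-dimensional subspace orthogonal to the
# ones vector.  Requires n >= k + 1.
random_centered_basis <- function(n, k) {
  if (n < k + 1L)
    stop("need at least ", k + 1L, " channels for a ", k,
         "-dimensional centred basis")
  g <- matrix(stats::rnorm(n * k), n, k)
  g <- sweep(g, 2L, colMeans(g))
  qr.Q(qr(g))[, seq_len(k), drop = FALSE]
}

# Random projection n_src -> n_tgt preserving pattern geometry as well as
# the dimensions allow (orthonormal columns; orthogonal when square).
random_projection <- function(n_src, n_tgt) {
  n <- max(n_src, n_tgt)
  q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  q[seq_len(n_src), seq_len(n_tgt), drop = FALSE]
}

rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
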