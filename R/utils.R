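# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

unit_vector <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot normalize a zero vector")
  x / nrm
}

# Cholesky factor (upper) of a symmetric PSD matrix, adding a small
# diagonal jitter proportional to the mean diagonal when the plain
# factorization fails. Errors if the matrix stays numerically singular.
safe_chol <- function(S, jitter = 1e-10, max_tries = 4L) {
  S <- (S + t(S)) / 2
  scale <- mean(diag(S))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  eps <- 0
  for (i in seq_len(max_tries + 1L)) {
    R <- tryCatch(chol(S + diag(eps, nrow(S))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    eps <- if (eps == 0) jitter * scale else eps * 100
  }
  stop("matrix is numerically singular even after diagonal jitter")
}

# Symmetric PSD square root via eigendecomposition; tolerates zero and
# slightly negative (round-off) eigenvalues, unlike chol().
psd_sqrt <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-12
  if (any(e$values < -max(tol, 1e-8))) {
    stop("matrix is not positive semidefinite")
  }
  lam <- pmax(e$values, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

upper_tri_values <- function(D) D[upper.tri(D)]

# Flip the sign of each column of U so its largest-magnitude entry is
# positive; V columns are flipped jointly. Removes SVD sign indeterminacy.
fix_signs <- function(U, V) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  list(U = U, V = V)
}

# Correlation of paired score vectors without re-centering: the inputs
# are already centered (ordinary case) or GLS-centered (whitened case).
score_correlation <- function(sx, sy) {
  den <- sqrt(sum(sx^2) * sum(sy^2))
  if (den == 0) return(NA_real_)
  sum(sx * sy) / den
}

# All permutations of 1..n (n small), as a list. Used by the exact
# enumeration fallback of the permutation tests.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- vector("list", factorial(n))
  i <- 0L
  for (k in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    tail <- setdiff(seq_len(n), k)
    for (p in rest) {
      i <- i + 1L
      out[[i]] <- c(k, tail[p])
    }
  }
  out
}

# Matrix of m random unit column vectors of dimension d.
random_unit_vectors <- function(d, m) {
  Z <- matrix(stats::rnorm(d * m), d, m)
  sweep(Z, 2, sqrt(colSums(Z^2)), "/")
}

as_numeric_matrix <- function(x, what = "input") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("%s must be a numeric matrix", what))
  }
  x
}
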