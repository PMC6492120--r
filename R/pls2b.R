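#' Two-block partial least squares, ordinary or phylogenetic
#'
#' Decomposes the cross-covariance between two blocks into successive
#' pairs of unit-norm axes with maximal score covariance. Both blocks
#' are column-centered (ordinary fit) or GLS-whitened against the
#' Brownian-motion covariance `C` (phylogenetic fit); the
#' cross-covariance `R = Xc' Yc / (n - 1)` is then decomposed by SVD.
#' The singular values are the score covariances of the paired latent
#' variables, in descending order, and `d_k^2 / sum(d^2)` is the
#' fraction of squared covariance carried by dimension k — the effect
#' size used on scree plots.
#'
#' Sign convention: each morphology loading vector is flipped so its
#' largest-magnitude entry is positive, with the paired environment
#' vector flipped jointly.
#'
#' @param X n x p block (morphology; centered, deliberately not scaled,
#'   so a shared size factor can surface on the first dimension).
#' @param Y n x q block (environment; standardize beforehand with
#'   [scale_unit_variance()] if the variables have heterogeneous units).
#' @param C optional n x n phylogenetic covariance; `NULL` fits the
#'   ordinary (non-phylogenetic) analysis.
#' @param tol threshold below which the cross-covariance is treated as
#'   exactly zero.
#' @return object of class `pls2b`: `dims`, loading matrices `u`
#'   (p x K) and `v` (q x K), singular values `d`, score matrices
#'   `scores_x`, `scores_y` (whitened scale in the phylogenetic case,
#'   with raw-centered projections in `scores_x_raw`/`scores_y_raw`),
#'   per-dimension score correlations `r`, effect sizes `effect`,
#'   and the `phylogenetic` flag.
#' @seealso [pls_permutation_test()], [pls_effect_sizes()]
#' @export
fit_2bpls <- function(X, Y, C = NULL, tol = 1e-12) {
  X <- as_numeric_matrix(X, "X"); Y <- as_numeric_matrix(Y, "Y")
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n < 3) stop("at least 3 rows are required")
  if (!is.null(C) && (nrow(C) != n || ncol(C) != n)) {
    stop("C must be n x n in the row order of X and Y")
  }
  p <- ncol(X); q <- ncol(Y)
  Xc <- center_or_whiten(X, C)
  Yc <- center_or_whiten(Y, C)
  R <- crossprod(Xc, Yc) / (n - 1)
  K <- min(p, q, n - 1L)
  if (max(abs(R)) < tol) {
    warning("zero cross-covariance: loadings set to canonical basis vectors")
    U <- diag(1, p)[, seq_len(K), drop = FALSE]
    V <- diag(1, q)[, seq_len(K), drop = FALSE]
    d <- rep(0, K)
  } else {
    s <- svd(R)
    d <- s$d[seq_len(K)]
    sg <- fix_signs(s$u[, seq_len(K), drop = FALSE],
                    s$v[, seq_len(K), drop = FALSE])
    U <- sg$U; V <- sg$V
  }
  rownames(U) <- colnames(X); rownames(V) <- colnames(Y)
  sx <- Xc %*% U; sy <- Yc %*% V
  r <- vapply(seq_len(K), function(k) score_correlation(sx[, k], sy[, k]),
              numeric(1))
  total <- sum(d^2)
  effect <- if (total > 0) d^2 / total else rep(NA_real_, K)
  out <- list(dims = K, u = U, v = V, d = d,
              scores_x = sx, scores_y = sy, r = r, effect = effect,
              phylogenetic = !is.null(C), n = n)
  if (!is.null(C)) {
    out$scores_x_raw <- sweep(X, 2, colMeans(X)) %*% U
    out$scores_y_raw <- sweep(Y, 2, colMeans(Y)) %*% V
  }
  structure(out, class = "pls2b")
}

#' Per-dimension effect sizes of a PLS fit
#'
#' @param result a `pls2b` object.
#' @return fractions `d_k^2 / sum(d^2)`, summing to 1.
#' @export
pls_effect_sizes <- function(result) {
  stopifnot(inherits(result, "pls2b"))
  total <- sum(result$d^2)
  if (total <= 0) stop("all singular values are zero: effect sizes undefined")
  result$d^2 / total
}

#' Permutation test for block association in 2B-PLS
#'
#' Permutes the rows of the (centered or whitened) second block and
#' refits; the p-value is `(count of permuted statistics >= observed
#' + 1) / (n_perm + 1)`. When all `n!` row permutations number no more
#' than `n_perm`, the test enumerates them exactly instead (p is then
#' `count / n!`, including the identity).
#'
#' @inheritParams fit_2bpls
#' @param n_perm number of random permutations (>= 99).
#' @param seed RNG seed.
#' @param statistic `"d1"` (first singular value, the default) or
#'   `"r1"` (first score correlation).
#' @return list with `p`, `observed`, `statistic`, `n_perm`, `exact`.
#' @export
pls_permutation_test <- function(X, Y, C = NULL, n_perm = 999L, seed = 1L,
                                 statistic = c("d1", "r1")) {
  statistic <- match.arg(statistic)
  if (n_perm < 99) stop("n_perm must be at least 99")
  X <- as_numeric_matrix(X, "X"); Y <- as_numeric_matrix(Y, "Y")
  n <- nrow(X)
  Xc <- center_or_whiten(X, C)
  Yc <- center_or_whiten(Y, C)
  stat_fun <- function(Yp) {
    R <- crossprod(Xc, Yp) / (n - 1)
    s <- svd(R, nu = 1L, nv = 1L)
    if (statistic == "d1") return(s$d[1])
    score_correlation(drop(Xc %*% s$u), drop(Yp %*% s$v))
  }
  obs <- stat_fun(Yc)
  eps <- 1e-12
  if (factorial(n) <= n_perm) {
    warning("n! <= n_perm: using exact enumeration of all row permutations")
    perms <- all_permutations(n)
    stats <- vapply(perms, function(idx) stat_fun(Yc[idx, , drop = FALSE]),
                    numeric(1))
    p <- sum(stats >= obs - eps) / length(perms)
    return(list(p = p, observed = obs, statistic = statistic,
                n_perm = length(perms), exact = TRUE))
  }
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    if (stat_fun(Yc[idx, , drop = FALSE]) >= obs - eps) count <- count + 1L
  }
  list(p = (count + 1) / (n_perm + 1), observed = obs,
       statistic = statistic, n_perm = n_perm, exact = FALSE)
}

#' @export
print.pls2b <- function(x, ...) {
  cat(sprintf("%s two-block PLS: n=%d, %d dimensions\n",
              if (x$phylogenetic) "phylogenetic" else "ordinary",
              x$n, x$dims))
  tab <- data.frame(d = x$d, effect_pct = 100 * x$effect, r = x$r)
  print(round(tab, 4))
  invisible(x)
}
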