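#' Partial regression coefficients of traits on latitude and longitude
#'
#' Fits, for each trait, `trait ~ intercept + latitude + longitude` by
#' ordinary least squares (`C = NULL`) or generalized least squares
#' with weight `C^-1` (phylogenetic fit), and returns the p x 2 matrix
#' of partial regression coefficients. Each row is the local gradient
#' of that trait's fitted surface over geography, in trait units per
#' decimal degree.
#'
#' @param X n x p trait matrix (log scale for morphometric use).
#' @param G n x 2 coordinate matrix, columns (latitude, longitude) in
#'   decimal degrees.
#' @param C optional n x n phylogenetic covariance.
#' @return p x 2 coefficient matrix `B`.
#' @export
pgls_coefficients <- function(X, G, C = NULL) {
  X <- as_numeric_matrix(X, "X"); G <- as_numeric_matrix(G, "G")
  n <- nrow(X)
  if (nrow(G) != n || ncol(G) != 2) stop("G must be n x 2 (latitude, longitude)")
  if (n < 4) stop("at least 4 rows are required")
  D <- cbind(intercept = 1, G)
  Xw <- X; Dw <- D
  if (!is.null(C)) {
    if (nrow(C) != n || ncol(C) != n) stop("C must be n x n")
    L <- t(safe_chol(C))
    Xw <- forwardsolve(L, X)
    Dw <- forwardsolve(L, D)
  }
  qrD <- qr(Dw)
  if (qrD$rank < 3L) {
    stop("latitude and longitude are collinear: coefficients are not identifiable")
  }
  Bfull <- qr.coef(qrD, Xw)        # 3 x p
  B <- t(Bfull[2:3, , drop = FALSE])
  rownames(B) <- colnames(X)
  colnames(B) <- colnames(G) %||% c("latitude", "longitude")
  B
}

#' Multivariate spatial cline by reduced-rank regression
#'
#' Finds the linear combinations of traits with the steepest regression
#' slope over geography: the p x 2 matrix `B` of partial regression
#' coefficients on (latitude, longitude) is decomposed by SVD,
#' `B = U D W'`. The singular values are the maximal slopes (trait
#' units per degree) of the fitted surface, the columns of `U` are the
#' morphological loadings, and the columns of `W` are the unit
#' geographic directions of the corresponding gradients. For any unit
#' trait combination `u` the gradient norm `||B'u||` is bounded by
#' `d_1`, attained at `u_1`. Unlike a two-block PLS of traits against
#' coordinates — which chases the direction of maximal spatial spread
#' of the sample — this maximizes the slope itself, so an elongated
#' sampling range does not drag the first axis toward its long side.
#'
#' @inheritParams pgls_coefficients
#' @param tol threshold below which `B` is treated as exactly zero.
#' @return object of class `rrr`: `B`, singular values `d`, morphology
#'   loadings `u` (p x K), geographic directions `w` (2 x K), score
#'   matrices `scores_x` and `scores_g` (centered, or GLS-whitened in
#'   the phylogenetic case), score correlations `r`, effect sizes
#'   `effect = d_k^2 / sum(d^2)`, and the `phylogenetic` flag.
#' @export
fit_rrr <- function(X, G, C = NULL, tol = 1e-12) {
  B <- pgls_coefficients(X, G, C)
  p <- nrow(B)
  K <- min(p, 2L)
  if (max(abs(B)) < tol) {
    warning("zero coefficient matrix: loadings set to canonical basis vectors")
    U <- diag(1, p)[, seq_len(K), drop = FALSE]
    W <- diag(1, 2)[, seq_len(K), drop = FALSE]
    d <- rep(0, K)
  } else {
    s <- svd(B)
    d <- s$d[seq_len(K)]
    sg <- fix_signs(s$u[, seq_len(K), drop = FALSE],
                    s$v[, seq_len(K), drop = FALSE])
    U <- sg$U; W <- sg$V
  }
  rownames(U) <- rownames(B)
  rownames(W) <- colnames(B)
  Xc <- center_or_whiten(X, C)
  Gc <- center_or_whiten(as_numeric_matrix(G, "G"), C)
  sx <- Xc %*% U; sg_ <- Gc %*% W
  r <- vapply(seq_len(K), function(k) score_correlation(sx[, k], sg_[, k]),
              numeric(1))
  total <- sum(d^2)
  effect <- if (total > 0) d^2 / total else rep(NA_real_, K)
  structure(list(B = B, dims = K, d = d, u = U, w = W,
                 scores_x = sx, scores_g = sg_, r = r, effect = effect,
                 phylogenetic = !is.null(C), n = nrow(Xc)),
            class = "rrr")
}

#' Permutation test for the reduced-rank regression slope
#'
#' Mirrors [pls_permutation_test()]: the rows of the (whitened) trait
#' block are permuted against the coordinates and the first singular
#' value of the refitted coefficient matrix serves as the statistic.
#'
#' @inheritParams pgls_coefficients
#' @param n_perm number of random permutations (>= 99).
#' @param seed RNG seed.
#' @return list with `p`, `observed`, `n_perm`, `exact`.
#' @export
rrr_permutation_test <- function(X, G, C = NULL, n_perm = 999L, seed = 1L) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  X <- as_numeric_matrix(X, "X"); G <- as_numeric_matrix(G, "G")
  n <- nrow(X)
  # whiten once; the permuted fits are then plain OLS on whitened data
  Xw <- X; D <- cbind(1, G)
  if (!is.null(C)) {
    L <- t(safe_chol(C))
    Xw <- forwardsolve(L, X)
    D <- forwardsolve(L, D)
  }
  qrD <- qr(D)
  if (qrD$rank < 3L) stop("latitude and longitude are collinear")
  stat_fun <- function(Xp) {
    B <- t(qr.coef(qrD, Xp)[2:3, , drop = FALSE])
    svd(B, nu = 0L, nv = 0L)$d[1]
  }
  obs <- stat_fun(Xw)
  eps <- 1e-12
  if (factorial(n) <= n_perm) {
    warning("n! <= n_perm: using exact enumeration of all row permutations")
    perms <- all_permutations(n)
    stats <- vapply(perms, function(idx) stat_fun(Xw[idx, , drop = FALSE]),
                    numeric(1))
    return(list(p = sum(stats >= obs - eps) / length(perms), observed = obs,
                n_perm = length(perms), exact = TRUE))
  }
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    if (stat_fun(Xw[idx, , drop = FALSE]) >= obs - eps) count <- count + 1L
  }
  list(p = (count + 1) / (n_perm + 1), observed = obs,
       n_perm = n_perm, exact = FALSE)
}

#' @export
print.rrr <- function(x, ...) {
  cat(sprintf("%s reduced-rank regression: n=%d traits p=%d\n",
              if (x$phylogenetic) "phylogenetic" else "ordinary",
              x$n, nrow(x$B)))
  tab <- data.frame(slope = x$d, effect_pct = 100 * x$effect, r = x$r)
  print(round(tab, 4))
  invisible(x)
}
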