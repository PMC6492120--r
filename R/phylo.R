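#' Brownian-motion covariance matrix from a time-scaled tree
#'
#' Under Brownian motion on a tree with branch lengths proportional to
#' time, the expected covariance between two tips is the shared path
#' length from the root to their most recent common ancestor, and the
#' variance of a tip is its root-to-tip depth. Computed with
#' [ape::vcv.phylo()] and reordered to `species_order`.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param species_order optional character vector (subset of the tips)
#'   giving the row/column order; defaults to the tree's tip order.
#' @return symmetric n x n covariance matrix with species dimnames.
#' @export
tree_to_covariance <- function(tree, species_order = NULL) {
  validate_phylo_tree(tree)
  C <- ape::vcv.phylo(tree)
  ord <- species_order %||% tree$tip.label
  missing <- setdiff(ord, rownames(C))
  if (length(missing) > 0) {
    stop("species not in tree: ", paste(missing, collapse = ", "))
  }
  C[ord, ord, drop = FALSE]
}

#' Phylogenetic (GLS) mean
#'
#' Generalized least-squares estimate of the root state for each
#' column: `a = (1' C^-1 1)^-1 1' C^-1 X`. With `C` proportional to the
#' identity this reduces to the arithmetic column mean.
#'
#' @param X n x p numeric matrix.
#' @param C n x n phylogenetic covariance (see [tree_to_covariance()]).
#' @return numeric p-vector of GLS means.
#' @export
phylogenetic_mean <- function(X, C) {
  X <- as_numeric_matrix(X, "X")
  n <- nrow(X)
  if (nrow(C) != n || ncol(C) != n) stop("C must be n x n")
  R <- safe_chol(C)
  # solve C z = [1 X] through the Cholesky factor
  rhs <- cbind(1, X)
  z <- backsolve(R, forwardsolve(t(R), rhs))
  drop(z[, -1, drop = FALSE] |> colSums()) / sum(z[, 1])
}

#' GLS whitening of a trait block
#'
#' Removes the phylogenetic mean and rotates by the inverse Cholesky
#' factor of `C`: `Xw = L^-1 (X - 1 a')` with `L L' = C`. Ordinary
#' cross-products of whitened blocks then equal the GLS cross-products
#' of the raw blocks, which is the algebraic engine behind the
#' phylogenetic PLS and reduced-rank regression fits.
#'
#' @inheritParams phylogenetic_mean
#' @return n x p whitened matrix, with the GLS mean attached as
#'   attribute `"gls_mean"`.
#' @export
gls_whiten <- function(X, C) {
  X <- as_numeric_matrix(X, "X")
  a <- phylogenetic_mean(X, C)
  L <- t(safe_chol(C))
  Xc <- sweep(X, 2, a)
  Xw <- forwardsolve(L, Xc)
  dimnames(Xw) <- dimnames(X)
  attr(Xw, "gls_mean") <- a
  Xw
}

# Center (C = NULL) or GLS-whiten (C given) a block; shared by the PLS
# and RRR fits.
center_or_whiten <- function(X, C = NULL) {
  X <- as_numeric_matrix(X, "block")
  if (is.null(C)) {
    sweep(X, 2, colMeans(X))
  } else {
    gls_whiten(X, C)
  }
}
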