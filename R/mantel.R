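.EARTH_RADIUS_KM <- 6371.0088  # mean Earth radius

#' Great-circle distance matrix between localities
#'
#' Haversine distances on a sphere of radius 6371.0088 km. Coordinates
#' are (latitude, longitude) in decimal degrees.
#'
#' @param coords m x 2 matrix, columns (latitude, longitude).
#' @return symmetric m x m matrix of distances in kilometres, zero
#'   diagonal.
#' @export
geodesic_distance_matrix <- function(coords) {
  coords <- as_numeric_matrix(coords, "coords")
  if (ncol(coords) != 2) stop("coords must have 2 columns (latitude, longitude)")
  if (anyNA(coords)) stop("missing coordinates")
  if (any(abs(coords[, 1]) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(coords[, 2]) > 180)) stop("longitude outside [-180, 180]")
  # geosphere expects (lon, lat); radius in km yields km directly
  D <- geosphere::distm(coords[, c(2, 1), drop = FALSE],
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = .EARTH_RADIUS_KM))
  dimnames(D) <- list(rownames(coords), rownames(coords))
  (D + t(D)) / 2
}

#' Euclidean phenotypic distance matrix
#'
#' Pairwise Euclidean distances between specimen (or species) trait
#' vectors, on the raw or natural-log scale. Missing cells are refused:
#' impute first with [em_impute()].
#'
#' @param X m x p complete trait matrix.
#' @param log_scale compute distances on log-transformed values.
#' @return symmetric m x m distance matrix.
#' @export
phenotype_distance_matrix <- function(X, log_scale = FALSE) {
  X <- as_numeric_matrix(X, "X")
  if (anyNA(X)) stop("missing cells in trait matrix: run em_impute() first")
  if (log_scale) X <- log_transform(X)
  as.matrix(stats::dist(X))
}

#' Mantel permutation test of matrix association
#'
#' Pearson correlation of the upper-triangle entries of two distance
#' matrices, with a permutation null obtained by jointly permuting the
#' rows and columns of the second matrix. The p-value is one-sided for
#' positive association — the directional alternative under isolation
#' by distance — and equals `(count >= observed + 1) / (n_perm + 1)`.
#'
#' @param D1,D2 symmetric zero-diagonal distance matrices of equal size
#'   (m >= 4).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return object of class `mantel_result` with `r`, `p`, `n_perm`, `n`.
#' @export
mantel_test <- function(D1, D2, n_perm = 10000L, seed = 1L) {
  D1 <- as_numeric_matrix(D1, "D1"); D2 <- as_numeric_matrix(D2, "D2")
  m <- nrow(D1)
  if (any(dim(D1) != c(m, m)) || any(dim(D2) != c(m, m))) {
    stop("D1 and D2 must be square matrices of equal size")
  }
  if (m < 4) stop("at least 4 rows are required")
  for (D in list(D1, D2)) {
    if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
    if (max(abs(diag(D))) > 1e-8) stop("distance matrix must have zero diagonal")
  }
  v1 <- upper_tri_values(D1)
  v2 <- upper_tri_values(D2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("constant off-diagonal distances: correlation undefined")
  }
  r <- stats::cor(v1, v2)
  set.seed(seed)
  count <- 0L
  eps <- 1e-12
  for (b in seq_len(n_perm)) {
    idx <- sample.int(m)
    rp <- stats::cor(v1, upper_tri_values(D2[idx, idx]))
    if (rp >= r - eps) count <- count + 1L
  }
  structure(list(r = r, p = (count + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm), n = m),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}
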