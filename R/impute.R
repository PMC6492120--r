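#' EM imputation of missing measurements under a multivariate normal
#'
#' Iterates maximum-likelihood estimation of the mean vector and
#' covariance matrix with expectation of the missing cells: the E-step
#' replaces the missing entries of each row by their conditional
#' expectation given the row's observed entries under the current
#' `(mu, Sigma)`, the M-step re-estimates `mu` and `Sigma` from the
#' completed matrix including the conditional-covariance correction
#' term of the standard missing-data EM. Rows are processed grouped by
#' missingness pattern. `Sigma` uses the maximum-likelihood denominator
#' `1/n` and is ridge-regularized whenever `p >= n` or it turns
#' numerically singular, which is the generic situation for
#' within-species craniodental data where traits outnumber specimens.
#'
#' @param x numeric matrix with `NA`s; every column needs >= 2 observed
#'   values and every row >= 1.
#' @param tol convergence tolerance on the maximal absolute change of
#'   any imputed value between iterations.
#' @param max_iter iteration cap; hitting it sets `converged = FALSE`
#'   rather than raising an error.
#' @param ridge diagonal regularization added to `Sigma` when needed;
#'   default `1e-6 * mean(diag(Sigma))`, recomputed each M-step.
#' @return an object of class `em_imputation`: `completed` (matrix with
#'   no missing cells, equal to `x` wherever `x` was observed), `mu`,
#'   `Sigma`, `n_iter`, `converged`, `max_delta`, and `delta_trace`
#'   (per-iteration `max_delta`, for convergence diagnostics).
#' @export
em_impute <- function(x, tol = 1e-6, max_iter = 100L, ridge = NULL) {
  x <- as_numeric_matrix(x, "x")
  n <- nrow(x); p <- ncol(x)
  miss <- is.na(x)
  if (any(rowSums(!miss) == 0)) stop("row with no observed value")
  if (any(colSums(!miss) < 2)) {
    stop("every column needs at least 2 observed values")
  }
  if (!any(miss)) {
    mu <- colMeans(x)
    Sigma <- crossprod(sweep(x, 2, mu)) / n
    return(structure(list(completed = x, mu = mu, Sigma = Sigma,
                          n_iter = 0L, converged = TRUE, max_delta = 0,
                          delta_trace = numeric(0)),
                     class = "em_imputation"))
  }

  # start from column-mean completion
  mu <- colMeans(x, na.rm = TRUE)
  comp <- x
  comp[miss] <- mu[col(x)[miss]]

  pattern <- apply(miss, 1, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(n), pattern)

  regularize <- function(S) {
    lambda <- ridge %||% (1e-6 * mean(diag(S)))
    if (p >= n || inherits(tryCatch(chol(S), error = identity), "error")) {
      S <- S + diag(lambda, p)
    }
    S
  }

  mu <- colMeans(comp)
  Sigma <- regularize(crossprod(sweep(comp, 2, mu)) / n)

  delta_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    old_imputed <- comp[miss]
    correction <- matrix(0, p, p)
    for (g in names(groups)) {
      if (g == "") next
      rows <- groups[[g]]
      mi <- as.integer(strsplit(g, ",", fixed = TRUE)[[1]])
      oi <- setdiff(seq_len(p), mi)
      Soo <- Sigma[oi, oi, drop = FALSE]
      Som <- Sigma[oi, mi, drop = FALSE]
      R <- safe_chol(Soo)
      beta <- backsolve(R, forwardsolve(t(R), Som))      # Soo^-1 Som
      resid <- sweep(x[rows, oi, drop = FALSE], 2, mu[oi])
      comp[rows, mi] <- matrix(mu[mi], length(rows), length(mi),
                               byrow = TRUE) + resid %*% beta
      Cc <- Sigma[mi, mi, drop = FALSE] - crossprod(Som, beta)
      correction[mi, mi] <- correction[mi, mi] + length(rows) * Cc
    }
    mu <- colMeans(comp)
    Sigma <- regularize((crossprod(sweep(comp, 2, mu)) + correction) / n)
    max_delta <- max(abs(comp[miss] - old_imputed))
    delta_trace <- c(delta_trace, max_delta)
    if (max_delta < tol) { converged <- TRUE; break }
  }

  structure(list(completed = comp, mu = mu, Sigma = (Sigma + t(Sigma)) / 2,
                 n_iter = iter, converged = converged,
                 max_delta = delta_trace[length(delta_trace)],
                 delta_trace = delta_trace),
            class = "em_imputation")
}

#' @export
print.em_imputation <- function(x, ...) {
  cat(sprintf("em_imputation: %d iterations, converged=%s, max_delta=%.3g\n",
              x$n_iter, x$converged, x$max_delta))
  invisible(x)
}
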