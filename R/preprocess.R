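#' Natural-log transform of positive measurements
#'
#' Observed cells are replaced by their natural logarithm; missing
#' cells stay missing. All between-individual and between-species
#' analyses in this package operate on the log scale, where linear
#' measurement ratios become additive contrasts.
#'
#' @param x numeric matrix of strictly positive measurements (NAs allowed).
#' @return matrix of the same shape.
#' @export
log_transform <- function(x) {
  x <- as_numeric_matrix(x, "measurements")
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("nonpositive value at row %d, column '%s'",
                 bad[1, 1], colnames(x)[bad[1, 2]] %||% as.character(bad[1, 2])))
  }
  log(x)
}

#' Scale each column to unit variance
#'
#' Divides every column by its standard deviation (denominator n - 1).
#' Centering is left to the downstream fit, mirroring how the
#' environmental block is standardized to remove measurement-scale
#' differences before a two-block fit.
#'
#' @param x numeric matrix with at least 2 rows and no missing cells.
#' @return matrix whose columns have standard deviation 1.
#' @export
scale_unit_variance <- function(x) {
  x <- as_numeric_matrix(x, "block")
  if (anyNA(x)) stop("missing cells: impute before scaling")
  s <- apply(x, 2, stats::sd)
  zero <- s <= 0 | !is.finite(s)
  if (any(zero)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[zero] %||% which(zero), collapse = ", "))
  }
  sweep(x, 2, s, "/")
}

# Per (species, sex, trait) means, ignoring missing cells.
.sex_means <- function(tab) {
  meta <- tab$meta
  m <- tab$measurements
  sex <- tolower(as.character(meta$sex))
  if (anyNA(sex)) stop("sex is required for sex-aware operations")
  key <- interaction(meta$species, sex, drop = FALSE)
  list(species = meta$species, sex = sex, key = key, m = m)
}

#' Species means as the average of female and male means
#'
#' For each species and trait, the species mean is the arithmetic mean
#' of the female mean and the male mean — not the pooled specimen mean,
#' which would be biased toward the better-sampled sex. Cells where one
#' sex is entirely unobserved for a trait are returned as `NA` with a
#' warning.
#'
#' @param table a [specimen_table].
#' @param on_log_scale log-transform the measurements first (default
#'   `TRUE`; between-species analyses operate on the log scale).
#' @return species x trait matrix of means.
#' @export
species_means <- function(table, on_log_scale = TRUE) {
  stopifnot(inherits(table, "specimen_table"))
  m <- table$measurements
  if (on_log_scale) m <- log_transform(m)
  sex <- tolower(as.character(table$meta$sex))
  if (anyNA(sex)) stop("sex is required to form species means")
  species <- sort(unique(table$meta$species))
  out <- matrix(NA_real_, length(species), ncol(m),
                dimnames = list(species, colnames(m)))
  for (sp in species) {
    for (sx in c("female", "male")) {
      rows <- table$meta$species == sp & sex == sx
      mu <- if (any(rows)) colMeans(m[rows, , drop = FALSE], na.rm = TRUE)
            else rep(NaN, ncol(m))
      mu[is.nan(mu)] <- NA_real_
      out[sp, ] <- if (sx == "female") mu else (out[sp, ] + mu) / 2
    }
  }
  if (anyNA(out)) {
    warning("species-trait cell(s) with an entirely unobserved sex flagged as NA")
  }
  out
}

#' Remove sex differences within species
#'
#' Centers each specimen on its (species, sex) mean, per trait, so the
#' returned deviations are free of additive sexual dimorphism. Within
#' each (species, sex) group the deviations average to zero; a
#' singleton group contributes an exact zero (its only specimen equals
#' its own mean) and triggers a warning.
#'
#' @param table a [specimen_table].
#' @param on_log_scale log-transform first (default `TRUE`).
#' @return specimen x trait matrix of sex-centered deviations (NAs kept).
#' @export
remove_sex_effects <- function(table, on_log_scale = TRUE) {
  stopifnot(inherits(table, "specimen_table"))
  m <- table$measurements
  if (on_log_scale) m <- log_transform(m)
  sex <- tolower(as.character(table$meta$sex))
  if (anyNA(sex)) stop("sex is required to remove sex effects")
  key <- paste(table$meta$species, sex, sep = "\r")
  out <- m
  singleton <- FALSE
  for (g in unique(key)) {
    rows <- key == g
    if (sum(rows) == 1L) singleton <- TRUE
    mu <- colMeans(m[rows, , drop = FALSE], na.rm = TRUE)
    out[rows, ] <- sweep(m[rows, , drop = FALSE], 2, mu)
  }
  out[is.na(m)] <- NA_real_
  out[is.nan(out)] <- NA_real_
  if (singleton) {
    warning("singleton (species, sex) group(s): deviations are exactly 0 there")
  }
  out
}
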