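#' Species-level analysis dataset
#'
#' Aligned container for the between-species analyses: a morphology
#' block `X` (log-scale species means), an environment block `Y`, the
#' geographic coordinate pair `G` (latitude, longitude of the range
#' centroid), and a time-scaled tree whose tip set equals the species
#' list. Row order is identical across all components.
#'
#' @param species character vector of n species labels.
#' @param X n x p numeric matrix (morphology block).
#' @param Y n x q numeric matrix (environment block).
#' @param G n x 2 numeric matrix, columns latitude and longitude.
#' @param tree an [ape::phylo] with tip set equal to `species`.
#' @return object of class `species_dataset`.
#' @export
species_dataset <- function(species, X, Y, G, tree) {
  X <- as_numeric_matrix(X, "X"); Y <- as_numeric_matrix(Y, "Y")
  G <- as_numeric_matrix(G, "G")
  n <- length(species)
  if (anyDuplicated(species)) stop("duplicate species labels")
  if (n < 3) stop("at least 3 species are required")
  if (nrow(X) != n || nrow(Y) != n || nrow(G) != n || ncol(G) != 2) {
    stop("X, Y, G must have one row per species and G exactly 2 columns")
  }
  if (anyNA(X) || anyNA(Y) || anyNA(G)) {
    stop("species_dataset does not allow missing cells")
  }
  validate_phylo_tree(tree)
  if (!setequal(tree$tip.label, species)) {
    stop("tree tip set must equal the species list")
  }
  rownames(X) <- rownames(Y) <- rownames(G) <- species
  colnames(G) <- c("latitude", "longitude")
  structure(list(species = species, X = X, Y = Y, G = G, tree = tree),
            class = "species_dataset")
}

#' @export
print.species_dataset <- function(x, ...) {
  cat(sprintf("species_dataset: n=%d species, p=%d morphology, q=%d environment\n",
              length(x$species), ncol(x$X), ncol(x$Y)))
  invisible(x)
}

.species_labels <- function(x, what) {
  if (is.data.frame(x)) {
    if (!"species" %in% names(x)) {
      stop(sprintf("%s must carry a 'species' column", what))
    }
    return(as.character(x$species))
  }
  if (is.matrix(x) && !is.null(rownames(x))) return(rownames(x))
  stop(sprintf("%s must be a data frame with a 'species' column or a matrix with species rownames", what))
}

.species_matrix <- function(x, keep = NULL) {
  if (is.data.frame(x)) {
    num <- x[setdiff(names(x), "species")]
    m <- as.matrix(num)
    rownames(m) <- as.character(x$species)
  } else {
    m <- x
  }
  if (!is.null(keep)) m <- m[keep, setdiff(colnames(m), NULL), drop = FALSE]
  storage.mode(m) <- "double"
  m
}

#' Align species-level inputs into one canonical dataset
#'
#' Intersects the species sets of the morphology table, environment
#' table, coordinate table and tree, drops anything not shared by all
#' (and any species in `drop_species`, e.g. a geographic outlier
#' excluded from a spatial analysis) with a warning, prunes the tree,
#' and reorders every block to the canonical species order — the tip
#' order of the pruned tree after a deterministic postorder traversal —
#' so downstream matrices are reproducible regardless of input row
#' order.
#'
#' @param morph data frame with a `species` column plus numeric trait
#'   columns, or a matrix with species rownames.
#' @param env same conventions, environment variables.
#' @param geo same conventions; must provide `latitude` and `longitude`.
#' @param tree an [ape::phylo] tree.
#' @param drop_species optional character vector of species to exclude.
#' @return a [species_dataset].
#' @export
align_dataset <- function(morph, env, geo, tree, drop_species = NULL) {
  validate_phylo_tree(tree)
  labs <- list(morph = .species_labels(morph, "morph"),
               env = .species_labels(env, "env"),
               geo = .species_labels(geo, "geo"))
  for (nm in names(labs)) {
    if (anyDuplicated(labs[[nm]])) stop("duplicate species labels in ", nm)
  }
  shared <- Reduce(intersect, c(list(tree$tip.label), labs))
  shared <- setdiff(shared, drop_species)
  all_seen <- unique(c(tree$tip.label, unlist(labs)))
  dropped <- setdiff(all_seen, shared)
  if (length(dropped) > 0) {
    warning("dropping species absent from some input or excluded: ",
            paste(sort(dropped), collapse = ", "))
  }
  if (length(shared) < 3) stop("fewer than 3 species shared across inputs")
  tr <- ape::keep.tip(tree, shared)
  tr <- ape::reorder.phylo(tr, "postorder")
  canonical <- tr$tip.label
  Xm <- .species_matrix(morph); Ym <- .species_matrix(env)
  Gm <- .species_matrix(geo)
  gcols <- match(c("latitude", "longitude"), colnames(Gm))
  if (anyNA(gcols)) stop("geo must provide 'latitude' and 'longitude' columns")
  species_dataset(canonical,
                  Xm[canonical, , drop = FALSE],
                  Ym[canonical, , drop = FALSE],
                  Gm[canonical, gcols, drop = FALSE],
                  tr)
}
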