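#' Read a rooted time-scaled phylogeny from a Newick file
#'
#' Thin validating wrapper around [ape::read.tree()]. Branch lengths are
#' required (the Brownian-motion covariance is built from them), tip
#' labels must be unique, and lengths must be nonnegative.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt)
}

#' Parse a Newick string into a validated tree
#'
#' @param text a Newick string, terminated by a semicolon.
#' @return an [ape::phylo] tree.
#' @export
parse_newick <- function(text) {
  if (!grepl(";", text, fixed = TRUE)) {
    stop("Newick parse error: missing terminating semicolon")
  }
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("Newick parse error: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("Newick parse error: malformed tree string")
  validate_phylo_tree(tree)
}

validate_phylo_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge)) {
    stop("branch lengths are required on every edge")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  root <- ape::Ntip(tree) + 1L
  if (sum(tree$edge[, 1] == root) < 2L) {
    stop("root must have at least two children")
  }
  tree
}

#' Root-to-tip path lengths
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return named numeric vector of tip depths.
#' @export
tip_depths <- function(tree) {
  validate_phylo_tree(tree)
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d
}
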