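#' Read a rooted, time-calibrated tree from Newick
#'
#' Parses a Newick tree, requires branch lengths and unique tip labels, and
#' records (in attribute `ultrametric`) whether all root-to-tip path lengths
#' agree within `1e-6 * tree height`.
#'
#' @param path Newick file.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file")
  if (is.null(tree$edge.length)) stop("missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  attr(tree, "ultrametric") <- is_ultrametric(tree)
  tree
}

#' Write a tree to Newick
#' @param tree an `ape::phylo` tree.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

is_ultrametric <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) <= tol * max(d)
}

tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}

# reorder a named trait vector to tree tip order, with checks
align_trait <- function(tree, x, what = "trait") {
  if (is.null(names(x))) {
    if (length(x) != length(tree$tip.label))
      stop(what, " length does not match number of tips")
    names(x) <- tree$tip.label
    return(x)
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss))
    stop(what, " missing for tip(s): ", paste(miss, collapse = ", "))
  x[tree$tip.label]
}
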