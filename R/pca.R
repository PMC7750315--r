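#' PCA of standardized (row-centered) binned spectra
#'
#' Principal component analysis on the covariance of the bin matrix. Rows are
#' expected to be spectra already centered to zero mean reflectance (see
#' [center_and_bin()]); that row-centering is what removes total reflectance
#' as a dominant variable, so no per-column rescaling is applied here.
#' Component signs are fixed deterministically: each loading vector's
#' largest-magnitude element is made positive.
#'
#' @param binned sample-by-bin numeric matrix.
#' @return object of class `pca_result`: `scores`, `loadings`,
#'   `var_explained` (fractions, non-increasing), `bin_edges`, `center`.
#' @export
standardized_pca <- function(binned) {
  binned <- as.matrix(binned)
  if (nrow(binned) < 2) stop("PCA needs >= 2 samples")
  if (all(apply(binned, 2, function(c) max(c) - min(c)) < 1e-12))
    stop("rank-0 input: all rows identical")
  p <- stats::prcomp(binned, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2, flip, "*")
  p$x <- sweep(p$x, 2, flip, "*")
  structure(list(scores = p$x, loadings = p$rotation,
                 var_explained = p$sdev^2 / sum(p$sdev^2),
                 bin_edges = attr(binned, "edges"), center = p$center,
                 species = attr(binned, "species"),
                 morph = attr(binned, "morph")),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples x %d bins; PC1+PC2 explain %.2f%%\n",
              nrow(x$scores), nrow(x$loadings),
              100 * sum(x$var_explained[1:min(2, length(x$var_explained))])))
  invisible(x)
}

#' Species mean scores from a PCA
#'
#' Species point = mean of its individuals' scores on the first `k`
#' components; colour morphs are kept separate (key `species` or
#' `species:morph`).
#'
#' @param pca a `pca_result` carrying species/morph attributes.
#' @param k number of components (default 2).
#' @export
species_scores <- function(pca, k = 2) {
  stopifnot(inherits(pca, "pca_result"))
  if (is.null(pca$species)) stop("pca_result carries no species labels")
  key <- ifelse(is.na(pca$morph) | pca$morph == "NA", pca$species,
                paste(pca$species, pca$morph, sep = ":"))
  m <- do.call(rbind, lapply(split(seq_along(key), key), function(i)
    colMeans(pca$scores[i, seq_len(k), drop = FALSE])))
  m
}

#' Project a phylogeny into PC space (phylomorphospace)
#'
#' Internal-node coordinates are maximum-likelihood ancestral states under
#' Brownian motion for each component independently; edges are emitted for
#' plotting. Tip labels of the tree must all be present in `scores`.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param scores matrix of species coordinates (rownames = species), typically
#'   from [species_scores()].
#' @return object of class `phylomorphospace`: `tip_coords`, `node_coords`,
#'   `edges` (parent/child ids and labels).
#' @export
phylomorphospace <- function(tree, scores) {
  stopifnot(inherits(tree, "phylo"))
  scores <- as.matrix(scores)
  miss <- setdiff(tree$tip.label, rownames(scores))
  if (length(miss))
    stop("species missing from scores: ", paste(miss, collapse = ", "))
  scores <- scores[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  if (ntip == 1) {
    node_coords <- scores
    rownames(node_coords) <- "node_2"
  } else {
    node_coords <- matrix(
      unlist(lapply(seq_len(ncol(scores)), function(j)
        anc_ml(tree, stats::setNames(scores[, j], tree$tip.label)))),
      nrow = tree$Nnode)
    colnames(node_coords) <- colnames(scores)
    rownames(node_coords) <- paste0("node_", ntip + seq_len(tree$Nnode))
  }
  structure(list(tip_coords = scores, node_coords = node_coords,
                 edges = data.frame(parent = tree$edge[, 1],
                                    child = tree$edge[, 2]),
                 tree = tree),
            class = "phylomorphospace")
}
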