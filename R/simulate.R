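#' Simulate a pure-birth (Yule) tree
#'
#' A Yule tree conditioned on the number of tips, rescaled so the root-to-tip
#' height equals `height` time units (default 8, the age scale of a late-
#' Miocene plant radiation). Deterministic given `seed`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (per lineage per time unit).
#' @param seed integer seed (required).
#' @param height tree height after rescaling; NULL keeps the simulated scale.
#' @return ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed, height = 8) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  if (!is.null(height)) {
    tree$edge.length <- tree$edge.length * height / tree_height(tree)
  }
  attr(tree, "ultrametric") <- TRUE
  tree
}

# forward Yule simulation: number of lineages alive at time t
yule_tip_count <- function(birth_rate, t) {
  n <- 1L
  now <- 0
  repeat {
    now <- now + stats::rexp(1, n * birth_rate)
    if (now > t) return(n)
    n <- n + 1L
  }
}

#' Parametric reflectance-spectrum templates
#'
#' The generator emulates the corolla types seen in hawkmoth- vs fly-
#' pollinated nightshades: `"white"` - UV-absorbing (< 10% below 400 nm)
#' spectra rising logistically near 420 nm to a plateau drawn per individual
#' from U(50, 80)% of the white standard; `"dark"` - flat, low reflectance
#' with maximum near 20%; `"green"` - chlorophyll-like Gaussian peak near
#' 550 nm (used for leaves); `"freckled"` - pale green corollas.
#'
#' @param mode one of "white", "dark", "green", "freckled".
#' @param noise_sd per-individual Gaussian measurement noise, percent
#'   reflectance.
#' @param ... template parameter overrides (see defaults in the source).
#' @return object of class `spectrum_template`.
#' @export
spectrum_template <- function(mode = c("white", "dark", "green", "freckled"),
                              noise_sd = NULL, ...) {
  mode <- match.arg(mode)
  p <- switch(mode,
    white = list(base = 5, plateau_range = c(50, 80), rise_center = 420,
                 rise_width = 12, noise_sd = 1.5),
    dark = list(level_range = c(10, 16), tilt = 3, noise_sd = 1),
    green = list(base = 4, peak = 550, width = 40,
                 height_range = c(12, 18), noise_sd = 1),
    freckled = list(base = 10, peak = 550, width = 50,
                    height_range = c(8, 12), noise_sd = 1))
  if (!is.null(noise_sd)) p$noise_sd <- noise_sd
  extra <- list(...)
  p[names(extra)] <- extra
  structure(c(list(mode = mode), p), class = "spectrum_template")
}

template_curve <- function(tmpl, wl) {
  switch(tmpl$mode,
    white = {
      plateau <- stats::runif(1, tmpl$plateau_range[1], tmpl$plateau_range[2])
      tmpl$base + (plateau - tmpl$base) /
        (1 + exp(-(wl - tmpl$rise_center) / tmpl$rise_width))
    },
    dark = {
      level <- stats::runif(1, tmpl$level_range[1], tmpl$level_range[2])
      level + tmpl$tilt * (wl - min(wl)) / (max(wl) - min(wl))
    },
    {
      height <- stats::runif(1, tmpl$height_range[1], tmpl$height_range[2])
      tmpl$base + height * exp(-(wl - tmpl$peak)^2 / (2 * tmpl$width^2))
    })
}

#' Simulate reflectance spectra from a template
#'
#' Each individual gets a smooth template curve (with its own plateau/level
#' draw) plus seeded Gaussian noise, clipped to \[0, 100\]%.
#'
#' @param template a [spectrum_template()].
#' @param n_individuals number of individuals.
#' @param seed integer seed (required).
#' @param species species label.
#' @param tissue "corolla" or "leaf".
#' @param morph optional morph label.
#' @param n_replicates spectra per individual (default 1).
#' @param grid wavelength grid, nm.
#' @return a [spectrum_collection()].
#' @export
simulate_spectra <- function(template, n_individuals, seed, species = "sp",
                             tissue = "corolla", morph = NA_character_,
                             n_replicates = 1, grid = 300:700) {
  stopifnot(inherits(template, "spectrum_template"))
  set.seed(seed)
  specs <- list()
  for (i in seq_len(n_individuals)) {
    base <- template_curve(template, grid)
    for (r in seq_len(n_replicates)) {
      refl <- pmin(pmax(base + stats::rnorm(length(grid),
                                            sd = template$noise_sd), 0), 100)
      specs[[length(specs) + 1]] <- reflectance_spectrum(
        grid, refl, species = species, individual = sprintf("ind%02d", i),
        morph = morph, tissue = tissue,
        replicate = if (n_replicates > 1) sprintf("rep%d", r) else
          NA_character_)
    }
  }
  spectrum_collection(specs)
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Recursive Gaussian increments with variance `sigma2 *` branch length; true
#' internal-node values are returned for recovery scoring.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param sigma2 BM rate (>= 0).
#' @param root root state.
#' @param seed integer seed (required).
#' @return list with named `tips` and `nodes` vectors.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, root = 0, seed) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  val <- numeric(nn)
  val[ntip + 1] <- root
  po <- reorder(tree, "postorder")
  for (i in rev(seq_len(nrow(po$edge)))) {   # preorder
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    val[ch] <- val[p] + stats::rnorm(1, 0,
                                     sqrt(sigma2 * po$edge.length[i]))
  }
  list(tips = stats::setNames(val[seq_len(ntip)], tree$tip.label),
       nodes = stats::setNames(val[(ntip + 1):nn],
                               paste0("node_", (ntip + 1):nn)))
}

#' Simulate an ordered trait under the threshold model
#'
#' A BM liability (rate 1) is simulated on the tree and cut at the supplied
#' strictly increasing thresholds; a liability exactly at a threshold is
#' assigned to the upper category. True liabilities are retained.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param thresholds strictly increasing cut points (first conventionally 0).
#' @param seed integer seed (required).
#' @param root root liability.
#' @return list: `zones` (named tip categories), `liabilities` (tips),
#'   `node_liabilities`.
#' @export
simulate_threshold_trait <- function(tree, thresholds = c(0, 1), seed,
                                     root = 0) {
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  bm <- simulate_bm_trait(tree, sigma2 = 1, root = root, seed = seed)
  cat_of <- function(x) 1L + rowSums(outer(x, thresholds, ">="))
  list(zones = stats::setNames(cat_of(bm$tips), names(bm$tips)),
       liabilities = bm$tips, node_liabilities = bm$nodes,
       thresholds = thresholds)
}

#' Simulate a complete two-clade study scenario
#'
#' The default scenario mirrors the scale and structure the analysis assumes:
#' 11 species on a height-8 Yule tree; the smaller of the two clades
#' descending from the root is white-flowered and hawkmoth-pollinated (humid
#' lowlands), the larger is dark-flowered and fly-pollinated (alpine /
#' high-latitude); 4-11 individuals per species with one corolla spectrum
#' each; two leaf spectra per species form the background pool. Ordered
#' environmental zones are generated by thresholding a BM liability offset by
#' clade (white clade toward zone 1, dark clade toward zones 2-3), so zone and
#' pollination mode are phylogenetically linked as in the study system. Fully
#' reproducible from (parameters, seed).
#'
#' @param n_species number of species (default 11).
#' @param seed integer seed (required).
#' @param inds_range range of individuals per species (default c(4, 11)).
#' @param height tree height (default 8).
#' @param birth_rate Yule rate (default 1).
#' @param noise_sd spectral noise, percent (default: template defaults).
#' @return list: `tree`, `spectra` (corollas), `leaves`, `metadata`
#'   (species, mode, zone, clade, n_individuals), `seed`.
#' @export
simulate_scenario <- function(n_species = 11, seed, inds_range = c(4, 11),
                              height = 8, birth_rate = 1, noise_sd = NULL) {
  tree <- simulate_tree(n_species, birth_rate, seed = seed, height = height)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  clade_tips <- lapply(kids, function(k) {
    if (k <= ntip) tree$tip.label[k]
    else tree$tip.label[unlist(phangorn_free_descendants(tree, k))]
  })
  smaller <- which.min(lengths(clade_tips))
  white_sp <- clade_tips[[smaller]]
  dark_sp <- setdiff(tree$tip.label, white_sp)
  set.seed(seed + 1)
  n_ind <- stats::setNames(sample(inds_range[1]:inds_range[2], ntip,
                                  replace = TRUE), tree$tip.label)
  specs <- list()
  leaves <- list()
  for (i in seq_len(ntip)) {
    sp <- tree$tip.label[i]
    tmpl <- spectrum_template(if (sp %in% white_sp) "white" else "dark",
                              noise_sd = noise_sd)
    coll <- simulate_spectra(tmpl, n_ind[[sp]], seed = seed + 10 + i,
                             species = sp)
    specs <- c(specs, unname(coll$spectra))
    leaf <- simulate_spectra(spectrum_template("green", noise_sd = noise_sd),
                             2, seed = seed + 1000 + i, species = sp,
                             tissue = "leaf")
    leaves <- c(leaves, unname(leaf$spectra))
  }
  # ordered zones: BM liability with clade offsets, cut at (0, 2.5)
  bm <- simulate_bm_trait(tree, sigma2 = 1, root = 0, seed = seed + 2)
  liab <- bm$tips + ifelse(names(bm$tips) %in% white_sp, -3, 2.5)
  zones <- 1L + rowSums(outer(liab, c(0, 2.5), ">="))
  metadata <- data.frame(
    species = tree$tip.label,
    mode = ifelse(tree$tip.label %in% white_sp, "hawkmoth", "fly"),
    zone = as.integer(zones[tree$tip.label]),
    clade = ifelse(tree$tip.label %in% white_sp, "lowland", "andean"),
    n_individuals = as.integer(n_ind[tree$tip.label]),
    row.names = NULL)
  list(tree = tree, spectra = spectrum_collection(specs),
       leaves = spectrum_collection(leaves), metadata = metadata,
       seed = seed)
}

# tips descending from an internal node (no extra deps; simple stack walk)
phangorn_free_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}
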