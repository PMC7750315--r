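#' Bayesian threshold model for an ordered trait
#'
#' An ordered discrete trait (e.g. environmental zones 1 < 2 < 3) is modeled
#' as a latent Brownian "liability" cut at ordered thresholds. The liability
#' rate is fixed at 1 and the first threshold at 0 (identifiability); the
#' remaining thresholds have a uniform prior on `[0, prior_max]` (scaled to
#' tree height). A Gibbs sampler alternates (i) each node's liability given
#' its phylogenetic neighbours - a truncated normal at tips, whose liability
#' must stay inside the interval implied by the observed category, a plain
#' normal at internal nodes - and (ii) each free threshold uniformly over the
#' interval the current liabilities allow. A liability exactly at a threshold
#' belongs to the upper category.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param zones named integer vector of ordered tip categories (1..K).
#' @param generations Gibbs sweeps (default 10000).
#' @param burn_in sweeps discarded (default `generations %/% 5`).
#' @param thin keep every `thin`-th sweep (default 10).
#' @param seed integer seed (required).
#' @param prior_max upper bound of the uniform threshold prior (default 3 x
#'   tree height).
#' @param K number of categories in the ordered alphabet (default: the
#'   largest observed category; supply explicitly when not all categories are
#'   observed at the tips).
#' @return object of class `threshold_posterior`: posterior mean liabilities
#'   (tips + nodes), liability and threshold samples, per-node category
#'   posteriors, chain settings.
#' @export
threshold_mcmc <- function(tree, zones, generations = 10000,
                           burn_in = generations %/% 5, thin = 10, seed,
                           prior_max = NULL, K = NULL) {
  zones <- align_trait(tree, zones, "zones")
  if (any(zones != round(zones)) || any(zones < 1))
    stop("zones must be positive integers 1..K")
  if (is.null(K)) K <- max(zones)
  if (K < max(zones)) stop("K smaller than the largest observed category")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  if (is.null(prior_max)) prior_max <- 3 * tree_height(tree)
  # neighbour lists with BM precisions 1/branch length
  nb <- vector("list", nn)
  wt <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    w <- 1 / max(tree$edge.length[i], 1e-12)
    nb[[p]] <- c(nb[[p]], ch); wt[[p]] <- c(wt[[p]], w)
    nb[[ch]] <- c(nb[[ch]], p); wt[[ch]] <- c(wt[[ch]], w)
  }
  sw <- vapply(wt, sum, numeric(1))
  # thresholds: th[1] = 0 fixed; K-1 cut points overall
  th <- if (K >= 2) seq(0, by = 1, length.out = K - 1) else numeric(0)
  interval <- function(cat, th) {
    lo <- if (cat == 1) -Inf else th[cat - 1]
    hi <- if (cat == K) Inf else th[cat]
    c(lo, hi)
  }
  # feasible initialization: tips at category midpoints, nodes at tip mean
  l <- numeric(nn)
  for (i in seq_len(ntip)) {
    iv <- interval(zones[i], th)
    l[i] <- if (!is.finite(iv[1])) iv[2] - 1
    else if (!is.finite(iv[2])) iv[1] + 1
    else mean(iv)
  }
  l[(ntip + 1):nn] <- mean(l[seq_len(ntip)])
  set.seed(seed)
  keep <- seq(burn_in + 1, generations)
  keep <- keep[keep %% thin == 0]
  samp_l <- matrix(NA_real_, length(keep), nn)
  samp_th <- matrix(NA_real_, length(keep), max(K - 1, 1))
  samp_ll <- numeric(length(keep))
  ki <- 0L
  for (g in seq_len(generations)) {
    for (i in seq_len(nn)) {
      m <- sum(wt[[i]] * l[nb[[i]]]) / sw[i]
      s <- sqrt(1 / sw[i])
      if (i <= ntip) {
        iv <- interval(zones[i], th)
        plo <- stats::pnorm(iv[1], m, s)
        phi <- stats::pnorm(iv[2], m, s)
        if (phi - plo < 1e-12) {
          # far tail: clamp to the nearest feasible point
          l[i] <- min(max(m, iv[1] + 1e-9), iv[2] - 1e-9)
        } else {
          x <- stats::qnorm(stats::runif(1, plo, phi), m, s)
          l[i] <- min(max(x, iv[1] + 1e-12), iv[2] - 1e-12)
        }
      } else {
        l[i] <- stats::rnorm(1, m, s)
      }
    }
    if (K >= 3) {
      for (j in 2:(K - 1)) {
        below <- l[seq_len(ntip)][zones == j]
        above <- l[seq_len(ntip)][zones == j + 1]
        lo <- max(th[j - 1], if (length(below)) max(below) else -Inf, 0)
        hi <- min(if (j < K - 1) th[j + 1] else prior_max,
                  if (length(above)) min(above) else Inf, prior_max)
        if (hi > lo) th[j] <- stats::runif(1, lo, hi)
      }
    }
    if (g > burn_in && g %% thin == 0) {
      ki <- ki + 1L
      samp_l[ki, ] <- l
      samp_th[ki, ] <- if (K >= 2) th else NA_real_
      samp_ll[ki] <- sum(stats::dnorm(
        l[tree$edge[, 2]] - l[tree$edge[, 1]], 0,
        sqrt(pmax(tree$edge.length, 1e-12)), log = TRUE))
    }
  }
  colnames(samp_l) <- c(tree$tip.label,
                        paste0("node_", (ntip + 1):nn))
  # per-node category posterior, categorizing each retained sample with its
  # own thresholds (liability == threshold goes to the upper category)
  categorize <- function(x, th) 1L + rowSums(outer(x, th, ">="))
  node_cat <- matrix(0, nn - ntip, K,
                     dimnames = list(paste0("node_", (ntip + 1):nn),
                                     seq_len(K)))
  for (s in seq_len(nrow(samp_l))) {
    cats <- categorize(samp_l[s, (ntip + 1):nn], samp_th[s, seq_len(K - 1)])
    for (c in seq_len(K)) node_cat[, c] <- node_cat[, c] + (cats == c)
  }
  node_cat <- node_cat / nrow(samp_l)
  structure(list(liability_mean = colMeans(samp_l),
                 liability_samples = samp_l,
                 threshold_samples = samp_th,
                 loglik_trace = samp_ll,
                 node_category_posterior = node_cat,
                 zones = zones, K = K,
                 settings = list(generations = generations,
                                 burn_in = burn_in, thin = thin, seed = seed,
                                 prior_max = prior_max)),
            class = "threshold_posterior")
}

#' @export
print.threshold_posterior <- function(x, ...) {
  cat(sprintf("<threshold_posterior> K = %d categories, %d retained samples, %d generations\n",
              x$K, nrow(x$liability_samples), x$settings$generations))
  invisible(x)
}
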