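# Coordinates of loci in the metric's native space: log-catch (Delta f) space
# for the RNL metric, the (u, v) opponency plane for the fly metric. Group
# centroids are taken in these spaces so a centroid-to-centroid distance is
# itself a JND (rnl) or an opponency-plane distance (fly_euclid).
loci_coords <- function(loci, metric) {
  if (metric == "rnl") {
    t(vapply(loci, function(l) {
      if (length(l$q) != 3) stop("rnl metric requires trichromat loci")
      if (any(l$q <= 0)) stop("non-positive quantum catch")
      log(l$q)
    }, numeric(3)))
  } else {
    t(vapply(loci, function(l) fly_uv(l), numeric(2)))
  }
}

centroid_distance <- function(coords, ia, ib, metric, e) {
  d <- colMeans(coords[ia, , drop = FALSE]) -
    colMeans(coords[ib, , drop = FALSE])
  if (metric == "rnl") rnl_from_df(d, e) else sqrt(sum(d^2))
}

#' Bootstrapped colour distance between two groups
#'
#' For each replicate, samples are resampled with replacement within each
#' group, group centroids are computed in the metric's native space (log-catch
#' space for `"rnl"`, the opponency plane for `"fly_euclid"`), and the
#' centroid-to-centroid distance is recorded. Reports the replicate mean and a
#' percentile confidence interval. Deterministic given `seed`.
#'
#' @param loci list of `color_locus` objects.
#' @param groups character vector of group labels, one per locus.
#' @param pair length-2 character vector naming the two groups to compare.
#' @param metric "rnl" (JND, trichromat) or "fly_euclid" (opponency plane).
#' @param noise a [noise_model()]; required for `"rnl"`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed (required).
#' @param conf confidence level for the percentile interval (default 0.95).
#' @return one-row data frame: pair, metric, observed, mean, lo, hi, n_boot,
#'   seed.
#' @export
boot_group_distance <- function(loci, groups, pair,
                                metric = c("rnl", "fly_euclid"),
                                noise = NULL, n_boot = 1000, seed,
                                conf = 0.95) {
  metric <- match.arg(metric)
  stopifnot(length(groups) == length(loci), length(pair) == 2)
  if (metric == "rnl" && is.null(noise)) stop("rnl metric requires noise")
  e <- if (metric == "rnl") noise$e else NULL
  ia <- which(groups == pair[1]); ib <- which(groups == pair[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need >= 2 samples for the bootstrap")
  coords <- loci_coords(loci, metric)
  obs <- centroid_distance(coords, ia, ib, metric, e)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    centroid_distance(coords, sample(ia, replace = TRUE),
                      sample(ib, replace = TRUE), metric, e)
  }, numeric(1))
  qs <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  data.frame(group_a = pair[1], group_b = pair[2], metric = metric,
             observed = obs, mean = mean(reps), lo = qs[1], hi = qs[2],
             n_boot = n_boot, seed = seed, row.names = NULL)
}

#' Permutation test of between-group colour distance
#'
#' The observed statistic is the centroid-to-centroid distance for a pair of
#' groups (or, with `omnibus = TRUE`, the mean of that distance over all group
#' pairs). The null distribution is obtained by reshuffling the group labels
#' across all samples at the tested grouping level and recomputing the
#' statistic; `p = (1 + #(pseudo >= observed)) / (n_perm + 1)` (add-one
#' Monte-Carlo correction, so p is never exactly 0).
#'
#' @param loci list of `color_locus` objects.
#' @param groups character vector of group labels, one per locus.
#' @param metric "rnl" or "fly_euclid".
#' @param noise a [noise_model()] for the rnl metric.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed (required).
#' @param pairs optional list of length-2 character vectors restricting which
#'   group pairs are tested; default all pairs.
#' @param omnibus if TRUE, a single test of the mean over all pairs.
#' @return data frame with one row per pair (or a single `omnibus` row):
#'   observed statistic, p, significance flag at 0.05.
#' @export
permutation_test <- function(loci, groups, metric = c("rnl", "fly_euclid"),
                             noise = NULL, n_perm = 1000, seed,
                             pairs = NULL, omnibus = FALSE) {
  metric <- match.arg(metric)
  stopifnot(length(groups) == length(loci))
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (metric == "rnl" && is.null(noise)) stop("rnl metric requires noise")
  e <- if (metric == "rnl") noise$e else NULL
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop("permutation test needs >= 2 groups")
  if (is.null(pairs)) {
    cmb <- utils::combn(lev, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  coords <- loci_coords(loci, metric)
  # canonical sample order so p is invariant to input permutation
  ord <- order(groups)
  coords <- coords[ord, , drop = FALSE]
  groups <- groups[ord]
  stat <- function(g) {
    vapply(pairs, function(p)
      centroid_distance(coords, which(g == p[1]), which(g == p[2]),
                        metric, e), numeric(1))
  }
  obs <- stat(groups)
  set.seed(seed)
  pseudo <- matrix(NA_real_, n_perm, length(pairs))
  for (i in seq_len(n_perm)) pseudo[i, ] <- stat(sample(groups))
  if (omnibus) {
    p <- (1 + sum(rowMeans(pseudo) >= mean(obs))) / (n_perm + 1)
    return(data.frame(group_a = "omnibus", group_b = "omnibus",
                      metric = metric, observed = mean(obs), p = p,
                      significant = p < 0.05, n_perm = n_perm, seed = seed,
                      row.names = NULL))
  }
  p <- (1 + colSums(pseudo >= rep(obs, each = n_perm))) / (n_perm + 1)
  data.frame(group_a = vapply(pairs, `[`, character(1), 1),
             group_b = vapply(pairs, `[`, character(1), 2),
             metric = metric, observed = obs, p = p, significant = p < 0.05,
             n_perm = n_perm, seed = seed, row.names = NULL)
}

#' Pairwise discrimination summary
#'
#' Bootstrap confidence intervals and permutation p-values for every group
#' pair, in one tidy table (the two procedures are reported separately: the CI
#' comes from within-group resampling, the p-value from label permutation).
#'
#' @inheritParams permutation_test
#' @param n_boot bootstrap replicates per pair.
#' @export
color_discrimination <- function(loci, groups,
                                 metric = c("rnl", "fly_euclid"),
                                 noise = NULL, n_boot = 1000, n_perm = 1000,
                                 seed) {
  metric <- match.arg(metric)
  perm <- permutation_test(loci, groups, metric, noise, n_perm, seed)
  boots <- do.call(rbind, lapply(seq_len(nrow(perm)), function(i) {
    boot_group_distance(loci, groups, c(perm$group_a[i], perm$group_b[i]),
                        metric, noise, n_boot, seed + i)
  }))
  cbind(boots, p = perm$p, significant = perm$significant,
        n_perm = perm$n_perm)
}
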