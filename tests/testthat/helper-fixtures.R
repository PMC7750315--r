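# shared fixtures, all built in code

flat_spectrum <- function(value = 50, wl = 300:700, ...) {
  reflectance_spectrum(wl, rep(value, length(wl)), ...)
}

# step spectrum: low below `at`, high at and above
step_spectrum <- function(at = 500, lo = 0, hi = 100, wl = 300:700) {
  reflectance_spectrum(wl, ifelse(wl < at, lo, hi))
}

toy_grid <- 300:700

hawk_recs <- function(grid = toy_grid) default_receptor_set("hawkmoth", grid)
fly_recs <- function(grid = toy_grid) default_receptor_set("blowfly", grid)
d65 <- function(grid = toy_grid) load_illuminant("D65", grid)

# a locus with chosen adapted catches (trichromat by default)
mk_locus <- function(q, names = c("UV", "B", "G"), viewer = "hawkmoth",
                     species = "sp", individual = "i1") {
  color_locus(stats::setNames(q, names), viewer = viewer,
              lambda_max = stats::setNames(seq_along(q) * 100, names),
              species = species, individual = individual)
}

fly_q <- function(q) mk_locus(q, names = c("R7p", "R8p", "R7y", "R8y"),
                              viewer = "blowfly")

# small fixed trees
cherry3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
star4 <- function(bl = 1) {
  ape::read.tree(text = sprintf("(A:%g,B:%g,C:%g,D:%g);", bl, bl, bl, bl))
}

# 2-state analytic transition probability for an ER chain with rate q:
# P(same) = 1/2 + exp(-2qt)/2 (independent oracle for Mk tests)
p2_same <- function(q, t) 0.5 + 0.5 * exp(-2 * q * t)
p2_diff <- function(q, t) 0.5 - 0.5 * exp(-2 * q * t)

# brute-force Mk likelihood on a 3-taxon tree ((A:t1,B:t2):t3,C:t4); by
# enumerating both internal node states (uniform root prior)
brute_mk_3taxon <- function(states, q, t1, t2, t3, t4, k = 2) {
  stopifnot(k == 2)
  lik <- 0
  for (root in 1:2) for (inner in 1:2) {
    pr <- function(a, b, t) if (a == b) p2_same(q, t) else p2_diff(q, t)
    lik <- lik + 0.5 * pr(root, inner, t3) * pr(inner, states[1], t1) *
      pr(inner, states[2], t2) * pr(root, states[3], t4)
  }
  log(lik)
}

# exact marginal posterior of internal node states on the same 3-taxon tree
brute_mk_3taxon_marginals <- function(states, q, t1, t2, t3, t4) {
  joint <- matrix(0, 2, 2)   # root x inner
  pr <- function(a, b, t) if (a == b) p2_same(q, t) else p2_diff(q, t)
  for (root in 1:2) for (inner in 1:2) {
    joint[root, inner] <- 0.5 * pr(root, inner, t3) *
      pr(inner, states[1], t1) * pr(inner, states[2], t2) *
      pr(root, states[3], t4)
  }
  joint <- joint / sum(joint)
  list(root = rowSums(joint), inner = colSums(joint))
}

# exhaustive two-group permutation p-value oracle (centroid distance stat)
exhaustive_perm_p <- function(coords, groups, metric = "fly_euclid",
                              e = NULL) {
  n <- nrow(coords)
  lev <- sort(unique(groups))
  cdist <- function(g) {
    d <- colMeans(coords[g == lev[1], , drop = FALSE]) -
      colMeans(coords[g == lev[2], , drop = FALSE])
    if (metric == "rnl") pollicolor:::rnl_from_df(d, e) else sqrt(sum(d^2))
  }
  obs <- cdist(groups)
  na <- sum(groups == lev[1])
  combos <- utils::combn(n, na)
  ps <- apply(combos, 2, function(idx) {
    g <- rep(lev[2], n); g[idx] <- lev[1]
    cdist(g)
  })
  mean(ps >= obs - 1e-12)
}
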