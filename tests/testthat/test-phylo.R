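test_that("read_newick parses, validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  expect_length(tr$tip.label, 3)
  expect_equal(pollicolor:::tree_height(tr), 2)
  expect_true(attr(tr, "ultrametric"))
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f2)
  tr2 <- read_newick(f2)
  expect_identical(sort(tr2$tip.label), sort(tr$tip.label))
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  # errors: duplicate labels, missing branch lengths
  fdup <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,A:1):1,C:2);", fdup)
  expect_error(read_newick(fdup), "duplicate tip labels")
  fnb <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", fnb)
  expect_error(read_newick(fnb), "missing branch lengths")
})

test_that("BM fit matches the 2-taxon closed form", {
  tr <- ape::read.tree(text = "(A:1.5,B:1.5);")
  x <- c(A = 1, B = 5)
  f <- fit_continuous(tr, x, "BM")
  expect_equal(f$sigma2, (5 - 1)^2 / (4 * 1.5), tolerance = 1e-9)
  expect_equal(f$z0, 3, tolerance = 1e-9)
  expect_equal(f$k, 2L)
  expect_equal(f$AICc, -2 * f$logLik + 4 + 12 / (2 - 3), tolerance = 1e-9)
})

test_that("constant trait yields a degenerate-fit flag", {
  tr <- simulate_tree(8, seed = 1)
  f <- fit_continuous(tr, setNames(rep(2, 8), tr$tip.label), "BM")
  expect_true(f$degenerate)
})

test_that("OU with alpha -> 0 reproduces the BM likelihood", {
  tr <- simulate_tree(12, seed = 2)
  x <- simulate_bm_trait(tr, 1.5, 0, seed = 3)$tips
  bm <- fit_continuous(tr, x, "BM")
  ou <- fit_continuous(tr, x, "OU")
  expect_gte(ou$logLik, bm$logLik - 1e-4)
  # and EB nests BM too
  eb <- fit_continuous(tr, x, "EB")
  expect_gte(eb$logLik, bm$logLik - 1e-4)
  # BM likelihood is invariant to tip order
  x2 <- x[sample(length(x))]
  expect_equal(fit_continuous(tr, x2, "BM")$logLik, bm$logLik,
               tolerance = 1e-10)
})

test_that("BM sigma2 recovery across replicates (scaled-down)", {
  tr <- simulate_tree(100, seed = 4)
  s2 <- vapply(1:20, function(i)
    fit_continuous(tr, simulate_bm_trait(tr, 2, 0, seed = 100 + i)$tips,
                   "BM")$sigma2, numeric(1))
  expect_lt(abs(median(s2) - 2) / 2, 0.15)
})

test_that("anc_ml: midpoints, constants, GLS root and brute-force agreement", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  est <- anc_ml(tr, c(A = 0, B = 4))
  expect_equal(unname(est[1]), 2)
  # constant field propagates
  tr3 <- cherry3()
  estc <- anc_ml(tr3, c(A = 7, B = 7, C = 7))
  expect_equal(unname(estc), rep(7, 2))
  # root equals the GLS root of the BM fit
  tr2 <- simulate_tree(10, seed = 5)
  x <- simulate_bm_trait(tr2, 1, 0, seed = 6)$tips
  f <- fit_continuous(tr2, x, "BM")
  est2 <- anc_ml(tr2, x, f)
  expect_equal(unname(est2[1]), f$z0, tolerance = 1e-8)
  # brute-force numeric maximization of the joint BM likelihood on a cherry
  x3 <- c(A = 0, B = 2, C = 5)
  est3 <- anc_ml(tr3, x3)
  nll <- function(th) {
    -sum(dnorm(c(th[2] - th[1], x3[1] - th[2], x3[2] - th[2],
                 x3[3] - th[1]),
               0, sqrt(c(1, 1, 1, 2)), log = TRUE))
  }
  opt <- optim(c(0, 0), nll)
  expect_equal(unname(est3), opt$par, tolerance = 1e-3)
  # short cherry stem: node fuses with the root; brute-force oracle again
  trs <- ape::read.tree(text = "((A:1,B:1):0.0001,C:2);")
  ests <- anc_ml(trs, x3)
  nll_s <- function(th) {
    -sum(dnorm(c(th[2] - th[1], x3[1] - th[2], x3[2] - th[2],
                 x3[3] - th[1]),
               0, sqrt(c(0.0001, 1, 1, 2)), log = TRUE))
  }
  opt_s <- optim(c(1, 1), nll_s)
  expect_equal(unname(ests), opt_s$par, tolerance = 1e-2)
  expect_error(anc_ml(tr3, x3, fit_continuous(tr3, x3, "OU")), "BM")
})

test_that("Mk pruning matches brute-force enumeration on a 3-taxon tree", {
  tr <- cherry3()
  lv <- c("a", "b")
  for (q in c(0.1, 0.7, 2)) {
    Q <- matrix(c(-q, q, q, -q), 2, dimnames = list(lv, lv))
    for (st in list(c(1, 1, 2), c(1, 2, 1), c(2, 2, 2))) {
      states <- setNames(lv[st], c("A", "B", "C"))
      expect_equal(mk_loglik(tr, states, Q),
                   brute_mk_3taxon(st, q, 1, 1, 1, 2),
                   tolerance = 1e-8)
    }
  }
})

test_that("Mk fitting: nesting, degenerate case, rate recovery direction", {
  tr <- simulate_tree(20, seed = 7)
  set.seed(8)
  states <- setNames(sample(c("a", "b"), 20, replace = TRUE), tr$tip.label)
  er <- fit_mk(tr, states, "ER")
  ard <- fit_mk(tr, states, "ARD")
  expect_lte(er$logLik, ard$logLik + 1e-6)
  expect_equal(unname(rowSums(er$Q)), c(0, 0), tolerance = 1e-12)
  # all tips in one state: boundary flag
  same <- fit_mk(tr, setNames(rep("a", 20), tr$tip.label), "ER",
                 levels = c("a", "b"))
  expect_true(same$degenerate)
  expect_equal(same$rates, 0)
  expect_error(fit_mk(tr, states, "ER", levels = c("x", "y")),
               "absent from alphabet")
  # unknown tips are marginalized, likelihood still finite
  states_na <- states
  states_na[1] <- NA
  expect_true(is.finite(fit_mk(tr, states_na, "ER")$logLik))
})

test_that("compare_mk prefers the simplest adequate model", {
  tr <- simulate_tree(15, seed = 9)
  set.seed(10)
  states <- setNames(sample(c("a", "b"), 15, replace = TRUE), tr$tip.label)
  cmp <- compare_mk(tr, states)
  expect_identical(attr(cmp, "chosen"), "ER")
})

test_that("stochastic maps: zero-rate trivial case and exact marginals", {
  tr <- cherry3()
  # all tips one state with a degenerate fit: no transitions, root certain
  same_fit <- fit_mk(tr, setNames(rep("a", 3), c("A", "B", "C")), "ER",
                     levels = c("a", "b"))
  sm0 <- stochastic_map(tr, setNames(rep("a", 3), c("A", "B", "C")),
                        same_fit, n_maps = 50, seed = 11)
  expect_equal(sum(sm0$n_changes), 0)
  expect_equal(unname(sm0$node_posterior[1, "a"]), 1)
  # node posteriors from many maps match exact enumerated marginals
  states <- setNames(c("a", "b", "a"), c("A", "B", "C"))
  q <- 0.6
  Q <- matrix(c(-q, q, q, -q), 2, dimnames = list(c("a", "b"), c("a", "b")))
  fit <- structure(list(model = "ER", Q = Q, rates = q, logLik = NA,
                        k_params = 1, AIC = NA, levels = c("a", "b"),
                        states = states, tip_labels = tr$tip.label,
                        degenerate = FALSE), class = "mk_fit")
  sm <- stochastic_map(tr, states, fit, n_maps = 4000, seed = 12)
  ex <- brute_mk_3taxon_marginals(c(1, 2, 1), q, 1, 1, 1, 2)
  expect_equal(unname(sm$node_posterior["node_4", ]), ex$root,
               tolerance = 0.025, ignore_attr = TRUE)
  expect_equal(unname(sm$node_posterior["node_5", ]), ex$inner,
               tolerance = 0.025, ignore_attr = TRUE)
})

test_that("expected number of mapped changes grows with the rate", {
  tr <- simulate_tree(10, seed = 13)
  states <- setNames(rep(c("a", "b"), 5), tr$tip.label)
  means <- vapply(c(0.1, 1, 10), function(q) {
    Q <- matrix(c(-q, q, q, -q), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    fit <- structure(list(model = "ER", Q = Q, rates = q, logLik = NA,
                          k_params = 1, AIC = NA, levels = c("a", "b"),
                          states = states, tip_labels = tr$tip.label,
                          degenerate = FALSE), class = "mk_fit")
    mean(stochastic_map(tr, states, fit, n_maps = 60, seed = 14)$n_changes)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("branch-history sampler conditions correctly on endpoints", {
  # unequal-rate 2-state chain, short branch, forced change
  Q <- matrix(c(-1, 1, 3, -3), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  set.seed(15)
  for (i in 1:50) {
    h <- pollicolor:::sample_branch_history(Q, 1, 2, 0.5, c("a", "b"))
    expect_false(is.null(h))
    expect_identical(h$to[nrow(h)], "b")
    expect_true(all(diff(h$time) > 0))
  }
  # uniformization fallback agrees with rejection on event-count odds
  set.seed(16)
  n_rej <- vapply(1:300, function(i)
    nrow(pollicolor:::sample_branch_history(Q, 1, 2, 0.5, c("a", "b"))),
    integer(1))
  n_uni <- vapply(1:300, function(i)
    nrow(pollicolor:::sample_branch_history(Q, 1, 2, 0.5, c("a", "b"),
                                            max_retry = 0)),
    integer(1))
  expect_lt(abs(mean(n_rej == 1) - mean(n_uni == 1)), 0.1)
})

test_that("threshold MCMC respects constraints and recovers structure", {
  tr <- simulate_tree(10, seed = 17)
  sim <- simulate_threshold_trait(tr, c(0, 1), seed = 18)
  # make sure at least 2 categories present; rerun deterministic seed chosen
  post <- threshold_mcmc(tr, sim$zones, generations = 3000, burn_in = 500,
                         thin = 5, seed = 19)
  # every retained tip liability lies in its category's interval
  th <- post$threshold_samples
  for (s in seq_len(nrow(post$liability_samples))) {
    l <- post$liability_samples[s, seq_len(10)]
    z <- sim$zones[colnames(post$liability_samples)[seq_len(10)]]
    cut <- th[s, ]
    expect_true(all(l[z == 1] < cut[1]))
    if (post$K >= 2) expect_true(all(l[z == 2] >= cut[1]))
    if (post$K >= 3) {
      expect_true(all(l[z == 2] < cut[2]))
      expect_true(all(l[z == 3] >= cut[2]))
      expect_true(all(th[s, 2] > th[s, 1]))
    }
  }
  # category posteriors are probability vectors
  expect_equal(unname(rowSums(post$node_category_posterior)),
               rep(1, tr$Nnode), tolerance = 1e-12)
})

test_that("threshold MCMC: all tips in category 1 pins the root there", {
  tr <- simulate_tree(10, seed = 20)
  zones <- setNames(rep(1L, 10), tr$tip.label)
  post <- threshold_mcmc(tr, zones, generations = 5000, burn_in = 1000,
                         seed = 21, K = 2)
  expect_gt(mean(post$liability_samples[, "node_11"] < 0), 0.95)
  expect_gt(post$node_category_posterior["node_11", "1"], 0.95)
})

test_that("PGLS: self-correlation, star-tree Pearson, and OU nesting", {
  tr <- simulate_tree(12, seed = 22)
  x <- simulate_bm_trait(tr, 1, 0, seed = 23)$tips
  f <- pgls_corr(tr, x, x + 0, "BM")
  expect_equal(f$r, 1, tolerance = 1e-9)
  # star tree: r equals the ordinary Pearson correlation
  st <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(24)
  xs <- setNames(rnorm(6), st$tip.label)
  ys <- setNames(rnorm(6), st$tip.label)
  fs <- pgls_corr(st, xs, ys, "BM")
  expect_equal(fs$r, cor(xs, ys), tolerance = 1e-9)
  # OU never fits worse than BM (alpha -> 0 nests it)
  y2 <- simulate_bm_trait(tr, 1, 0, seed = 25)$tips
  fb <- pgls_corr(tr, x, y2, "BM")
  fo <- pgls_corr(tr, x, y2, "OU")
  expect_gte(fo$logLik, fb$logLik - 1e-4)
  expect_true(fo$p_value >= 0 && fo$p_value <= 1)
})

test_that("color_vector summarizes species loci along PC1", {
  # two clusters of hawkmoth catches separate with opposite signs
  loci <- c(lapply(1:3, function(i) mk_locus(c(1, 1, 1) + i * 1e-3,
                                             species = paste0("w", i))),
            lapply(1:3, function(i) mk_locus(c(0.4, 1.2, 1.6) + i * 1e-3,
                                             species = paste0("d", i))))
  names(loci) <- vapply(loci, function(l) l$species, character(1))
  cv <- color_vector(loci, "hawkmoth")
  expect_true(all(sign(cv[1:3]) != sign(cv[4:6])))
  expect_gte(attr(cv, "var_explained"), 0.5)
  # degenerate: identical loci
  same <- lapply(1:3, function(i) mk_locus(c(1, 1, 1),
                                           species = paste0("s", i)))
  names(same) <- paste0("s", 1:3)
  expect_warning(cv0 <- color_vector(same, "hawkmoth"), "degenerate")
  expect_true(attr(cv0, "degenerate"))
  expect_error(color_vector(same[1:2], "hawkmoth"), "at least 3")
  # fly variant runs on opponency distances
  fl <- lapply(1:4, function(i) fly_q(c(1 + 0.1 * i, 1, 1, 1 + 0.05 * i)))
  names(fl) <- paste0("f", 1:4)
  cvf <- color_vector(fl, "fly")
  expect_length(cvf, 4)
})
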