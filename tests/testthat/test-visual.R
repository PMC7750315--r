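test_that("receptor template peaks where built and decays away", {
  tpl <- receptor_template(520, toy_grid)
  expect_equal(toy_grid[which.max(tpl)], 520, tolerance = 1)
  expect_equal(max(tpl), 1)
  uv <- receptor_template(357, toy_grid)
  expect_lt(uv[toy_grid == 520], 0.05)
  expect_error(receptor_template(250), "300-700")
})

test_that("quantum catch matches a hand Riemann-sum oracle on a toy grid", {
  grid <- c(400, 500, 600)
  sens <- matrix(c(0.2, 1, 0.4), ncol = 1)
  recs <- receptor_set("toy", "X", lambda_max = 500, densities = 1,
                       grid = grid, sensitivities = sens)
  il <- illuminant(grid, c(1, 2, 1))
  spec <- reflectance_spectrum(grid, c(50, 80, 20))
  bkg <- reflectance_spectrum(grid, c(10, 10, 10))
  loc <- quantum_catch(spec, recs, il, bkg)
  # trapezoid rule by hand on the 2 intervals
  f <- c(0.5, 0.8, 0.2) * c(0.2, 1, 0.4) * c(1, 2, 1)
  Q_hand <- 100 * (f[1] + f[2]) / 2 + 100 * (f[2] + f[3]) / 2
  expect_equal(unname(loc$Q), Q_hand, tolerance = 1e-9)
})

test_that("von Kries adaptation: background identity and illuminant scale invariance", {
  leaf <- simulate_spectra(spectrum_template("green"), 1, seed = 2,
                           tissue = "leaf")$spectra[[1]]
  loc <- quantum_catch(leaf, hawk_recs(), d65(), leaf)
  expect_equal(unname(loc$q), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(unname(loc$r), rep(1 / 3, 3), tolerance = 1e-12)
  flower <- simulate_spectra(spectrum_template("white"), 1,
                             seed = 3)$spectra[[1]]
  il <- d65()
  il2 <- illuminant(il$wl, 2 * il$irradiance)
  q1 <- quantum_catch(flower, hawk_recs(), il, leaf)$q
  q2 <- quantum_catch(flower, hawk_recs(), il2, leaf)$q
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("integration is grid-converged for smooth spectra", {
  fine <- seq(300, 700, 0.5)
  flower <- simulate_spectra(spectrum_template("white", noise_sd = 0), 1,
                             seed = 4, grid = fine)$spectra[[1]]
  leaf <- simulate_spectra(spectrum_template("green", noise_sd = 0), 1,
                           seed = 5, grid = fine, tissue = "leaf")$spectra[[1]]
  Q1 <- quantum_catch(flower, hawk_recs(300:700), d65(300:700), leaf)$Q
  r2 <- default_receptor_set("hawkmoth", fine)
  Q2 <- quantum_catch(flower, r2, load_illuminant("D65", fine), leaf)$Q
  expect_true(all(abs(Q2 - Q1) / Q1 < 0.001))
})

test_that("Maxwell triangle geometry", {
  expect_equal(unname(maxwell_locus(mk_locus(c(1, 1, 1)))), c(0, 0))
  # pure-receptor vertex lies at distance sqrt(2/3)
  v <- maxwell_locus(mk_locus(c(1, 0, 0)))
  expect_equal(sqrt(sum(v^2)), sqrt(2 / 3), tolerance = 1e-12)
  # swapping r_UV and r_G negates x, leaves y
  a <- maxwell_locus(mk_locus(c(3, 2, 1)))
  b <- maxwell_locus(mk_locus(c(1, 2, 3)))
  expect_equal(unname(a), unname(b * c(-1, 1)))
  # physical loci stay inside the triangle (vertices at distance sqrt(2/3))
  set.seed(7)
  for (i in 1:20) {
    q <- runif(3)
    expect_lte(sqrt(sum(maxwell_locus(mk_locus(q))^2)), sqrt(2 / 3) + 1e-12)
  }
  expect_error(maxwell_locus(fly_q(c(1, 1, 1, 1))), "trichromat")
})

test_that("fly categorical model assigns quadrants and boundary", {
  expect_identical(fly_locus(fly_q(c(1, 1, 1, 1)))$category, "boundary")
  expect_identical(fly_locus(fly_q(c(2, 1, 2, 1)))$category, "fly-UV")
  expect_identical(fly_locus(fly_q(c(1, 2, 2, 1)))$category, "fly-blue")
  expect_identical(fly_locus(fly_q(c(1, 2, 1, 2)))$category, "fly-yellow")
  expect_identical(fly_locus(fly_q(c(2, 1, 1, 2)))$category, "fly-purple")
  # category invariant under positive scaling of all catches
  set.seed(8)
  for (i in 1:10) {
    q <- runif(4, 0.2, 3)
    c1 <- fly_locus(fly_q(q))$category
    c2 <- fly_locus(fly_q(q * runif(1, 0.1, 10)))$category
    expect_identical(c1, c2)
  }
})

test_that("fly Euclidean distance is a metric on the opponency plane", {
  a <- fly_q(c(1, 1, 1, 1))        # (0, 0)
  b <- fly_q(c(13, 7, 7, 3))       # u = 0.3, v = 0.4
  expect_equal(fly_distance(a, a), 0)
  expect_equal(fly_distance(a, b), 0.5, tolerance = 1e-12)
  expect_equal(fly_distance(a, b), fly_distance(b, a))
  hb <- fly_q(c(1, 1, 1, 1)); hb$viewer <- "hoverfly"
  expect_error(fly_distance(a, hb), "mixed viewers")
})

test_that("RNL noise and chromatic distance follow the receptor-noise model", {
  nm <- noise_model(stats::setNames(c(0.1, 0.23, 0.67), c("UV", "B", "G")),
                    weber = 0.1)
  expect_equal(unname(nm$e["G"]), 0.1)
  expect_equal(unname(nm$e["B"]), 0.1 * sqrt(0.67 / 0.23), tolerance = 1e-12)
  expect_equal(unname(nm$e["UV"]), 0.1 * sqrt(0.67 / 0.1), tolerance = 1e-12)
  a <- mk_locus(c(1.2, 0.8, 1.5))
  expect_equal(rnl_distance(a, a, nm), 0)
  # uniform scaling (achromatic shift) cancels
  b <- mk_locus(c(1.2, 0.8, 1.5) * 3.7)
  expect_equal(rnl_distance(a, b, nm), 0, tolerance = 1e-12)
  # symmetry and positivity
  cdl <- mk_locus(c(0.5, 1.1, 2))
  expect_equal(rnl_distance(a, cdl, nm), rnl_distance(cdl, a, nm))
  expect_gt(rnl_distance(a, cdl, nm), 0)
  # invariant to consistent receptor relabeling
  perm <- c(3, 1, 2)
  nm_p <- noise_model(stats::setNames(c(0.1, 0.23, 0.67)[perm],
                                      c("a", "b", "c")), weber = 0.1)
  a_p <- mk_locus(a$q[perm], names = c("a", "b", "c"))
  c_p <- mk_locus(cdl$q[perm], names = c("a", "b", "c"))
  expect_equal(rnl_distance(a_p, c_p, nm_p), rnl_distance(a, cdl, nm),
               tolerance = 1e-12)
  expect_error(rnl_distance(mk_locus(c(0, 1, 1)), a, nm), "non-positive")
})

test_that("achromatic contrast in the long-wave receptor", {
  nm <- noise_model(stats::setNames(c(0.1, 0.23, 0.67), c("UV", "B", "G")))
  bkg <- mk_locus(c(1, 1, 1))
  expect_equal(as.numeric(achromatic_contrast(bkg, bkg)), 0)
  expect_equal(as.numeric(achromatic_contrast(bkg, bkg, nm, "log_jnd")), 0)
  a <- mk_locus(c(1, 1, 3))
  expect_equal(as.numeric(achromatic_contrast(a, bkg, form = "michelson")),
               0.5)
  b <- mk_locus(c(1, 1, exp(1)))
  expect_equal(as.numeric(achromatic_contrast(b, bkg, nm, "log_jnd")), 10,
               tolerance = 1e-12)
})

test_that("bundled illuminants load and convert", {
  il <- load_illuminant("sunset", 300:700)
  expect_true(all(il$irradiance > 0))
  q <- energy_to_photon_flux(il)
  expect_equal(q$irradiance, il$irradiance * il$wl)
  expect_error(load_illuminant("nope"), "not found")
})
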