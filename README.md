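# pollicolor

Flower colour evolution through the eyes of pollinators.

`pollicolor` is an R package for analysing how corolla colour diversifies
across "pollinator climates" — geographic regimes dominated by different
pollinator groups (for example nocturnal hawkmoths in humid subtropical
lowlands versus carrion/dung flies in alpine and high-latitude habitats). It
is aimed at pollination biologists and phylogenetic comparative researchers
who have (a) reflectance spectra of corollas and leaves, (b) a dated
phylogeny, and (c) per-species metadata (pollination mode, ordered
environmental zone), and who want the whole chain from raw spectra to
comparative inference in one tested toolkit.

## What it computes

**Spectral processing.** Spectra are resampled to a common 1-nm grid, trimmed
to the insect-vision window (300–700 nm), smoothed by degree-2 local
regression (span 0.25), averaged by replicate/individual/species (colour
morphs kept separate), then mean-centered and binned into ten 40-nm intervals
for a shape PCA that removes total reflectance as a variable.

**Pollinator visual models.** Quantum catches are trapezoid-rule integrals of
reflectance × receptor sensitivity × illuminant photon flux, von Kries
adapted to a leaf background (background ↦ q = 1). For a trichromatic
hawkmoth (UV/B/G peaks 357/450/520 nm), loci are placed in the Maxwell
triangle and chromatic distances follow the receptor-noise-limited model

    dS = sqrt( (e1²(Δf3−Δf2)² + e2²(Δf3−Δf1)² + e3²(Δf2−Δf1)²)
               / ((e1e2)² + (e1e3)² + (e2e3)²) ),   Δf_i = ln(q_i^a / q_i^b),

with neural noise `e_i = ω √(η_max/η_i)` from receptor densities
(0.1, 0.23, 0.67) and Weber fraction ω = 0.1, so e = (0.2588, 0.1707, 0.1)
and 1 JND is the discrimination threshold. For flies, the categorical
opponency model assigns each locus to fly-UV / fly-blue / fly-yellow /
fly-purple from the signs of `u = (q_R7p − q_R8p)/(q_R7p + q_R8p)` and the
analogous `v`, with Euclidean (u, v) distances as graded conspicuousness.

**Discriminability statistics.** Bootstrapped centroid distances with
percentile CIs, and permutation tests with `p = (1 + #{pseudo ≥ obs})/(N+1)`.

**Phylogenetic comparative methods** (all likelihoods implemented
in-package): BM/OU/EB continuous-trait fits compared by AICc; joint-ML
ancestral states under BM; ER/SYM/ARD Mk fits by Felsenstein pruning;
stochastic character mapping (rejection sampling with uniformization
fallback); a Bayesian threshold model for ordered environmental zones (Gibbs
sampling of liabilities and thresholds); and PGLS correlation between
environmental liabilities and perceptual colour vectors with a
likelihood-ratio test of r = 0.

**Synthetic data.** A generator produces the whole stated world — Yule tree
(height 8), white UV-absorbing corollas (plateau 50–80%) on one clade, dark
(~20% max) corollas on the other, chlorophyll-like leaves, BM traits,
threshold-model zones — so the full pipeline is testable offline.

## Worked example

```r
library(pollicolor)

# a synthetic two-clade study: 11 species, hawkmoth-pollinated white flowers
# on one clade, fly-pollinated dark flowers on the other
scn  <- simulate_scenario(11, seed = 1)
proc <- aggregate_spectra(
  smooth_spectrum(trim_spectrum(scn$spectra), span = 0.25), "individual")
leaves <- smooth_spectrum(trim_spectrum(scn$leaves), span = 0.25)
grid <- proc$grid
leaf_mean <- reflectance_spectrum(grid,
  rowMeans(vapply(leaves$spectra, function(s) s$reflectance,
                  numeric(length(grid)))),
  species = "background", tissue = "leaf")

# hawkmoth colour loci under dusk light, adapted to the mean leaf
recs <- default_receptor_set("hawkmoth", grid)
tab  <- locus_table(proc, recs, load_illuminant("sunset", grid), leaf_mean)
head(tab[, c("species", "individual", "q_UV", "q_B", "q_G", "x", "y")], 3)
#>          species individual     q_UV      q_B      q_G         x         y
#> t1:ind01      t1      ind01 1.811780 6.590129 3.671750 0.1089311 0.2602505
#> t1:ind02      t1      ind02 1.979224 8.699486 4.867758 0.1313804 0.2770939
#> t1:ind03      t1      ind03 1.855807 7.854865 4.385969 0.1269164 0.2741984
```

Each row is one individual's von Kries adapted catches (q) and Maxwell-
triangle coordinates; white flowers sit between the blue and green vertices,
far from the (0, 0) adaptation point, exactly where highly conspicuous
hawkmoth flowers should.

```r
# are the two pollination modes discriminable to the moth?
nm <- noise_model(recs, weber = 0.1)
mode_of <- setNames(scn$metadata$mode, scn$metadata$species)
color_discrimination(attr(tab, "loci"), unname(mode_of[tab$species]),
                     metric = "rnl", noise = nm,
                     n_boot = 1000, n_perm = 1000, seed = 1)
#>   group_a  group_b     mean       lo       hi           p
#> 1     fly hawkmoth 7.383307 7.291731 7.464056 0.000999001
```

The white/dark contrast is ~7.4 JND (95% CI 7.29–7.46), far above the 1-JND
threshold, and the permutation p sits at its 1/1001 floor: the moth separates
the modes easily.

```r
# spectral-shape PCA and evolutionary model comparison of PC1
pc <- standardized_pca(binned_matrix(proc))
pc
#> <pca_result> 89 samples x 10 bins; PC1+PC2 explain 99.99%
compare_continuous(scn$tree, species_scores(pc)[scn$tree$tip.label, 1])
#>   model    sigma2    logLik k     AICc
#> 3    EB 718.37947 -36.54385 3 82.51627
#> 1    BM  68.60795 -44.94005 2 95.38011
#> 2    OU  68.60795 -44.94005 3 99.30868
```

(EB wins here because the synthetic colour split happens at the basal
divergence — an early burst by construction.)

The full chain — PCA, phylomorphospace, both fly models, Mk fitting with
stochastic mapping, threshold MCMC on zones, and PGLS of liability against
colour vectors — runs as one reproducible pipeline:

```r
run_pipeline(list(seed = 1), "out/")   # 10 stage CSVs + manifest.json
```

or from the shell via the CLI script:

```sh
Rscript inst/cli/pollicolor.R run-all --seed 1 --out out/
Rscript inst/cli/pollicolor.R simulate --seed 1 --out data/
```

## Documentation

The methods vignette (`vignettes/flower-color-evolution.Rmd`) documents the
models, their assumptions, all tunable parameters with defaults and units,
what the synthetic generator does and does not emulate, and the numerical
choices made where the methods were open.
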