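---
title: "Modeling flower colour evolution through pollinator eyes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling flower colour evolution through pollinator eyes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pollicolor` implements a complete analysis chain for studying the evolution
of floral colour across "pollinator climates": geographic regimes that differ
in which pollinators are available (for example, nocturnal hawkmoths in humid
subtropical lowlands versus saprophilous flies in alpine and high-latitude
habitats). The chain runs from raw corolla reflectance spectra, through the
perceptual spaces of the relevant pollinators, to phylogenetic comparative
inference about how colour and habitat occupancy evolved together. A
synthetic-data generator reproduces the statistical structure of such a study
so that every stage is testable without field data.

This vignette is the package's account of the models it implements, the
parameters that matter, the numerical choices made where the method
descriptions left them open, and what the test suite does and does not
establish.

# Spectral preprocessing

A reflectance spectrum is percent reflectance relative to a white standard on
a strictly increasing wavelength grid. The processing chain is:

1. **Resampling.** All spectra are linearly interpolated onto a common 1-nm
   grid covering the intersection of the measured ranges. Spectrometers
   typically record every 0.2 nm; 1 nm keeps integrals accurate while keeping
   files small, and the step is configurable in `spectrum_collection()`.
2. **Trimming** (`trim_spectrum()`) to the insect-vision window, 300-700 nm.
3. **Smoothing** (`smooth_spectrum()`) by local polynomial regression
   (degree 2, tricube weights - the standard LOESS family) with span 0.25,
   the smallest span that removes instrument noise while preserving spectral
   shape. Degree-2 local regression reproduces constants and straight lines
   exactly, which the tests verify. Negative fitted values are clipped to
   zero (reflectance is physical); raw negative noise is retained *before*
   smoothing so the fit is not biased.
4. **Averaging** (`aggregate_spectra()`) over replicates within individuals
   and individuals within species. Colour morphs of polymorphic species are
   never pooled: a polymorphic species contributes one spectrum per morph.
   Whether centering precedes or follows averaging is not fully determined by
   the method family this follows; here each *averaged* spectrum is centered.
5. **Centering and binning** (`center_and_bin()`) for shape PCA: each
   spectrum has its own mean subtracted - removing total reflectance
   (brightness) so only spectral *shape* remains - and is averaged within ten
   contiguous 40-nm bins (right-open except the last). Bin value is the mean,
   not the sum, so bin values stay on the reflectance scale.

`standardized_pca()` then performs PCA on the covariance of the bin matrix.
"Standardized" here means row-centered spectra, not column z-scoring: the
point of the standardization is to remove brightness, and the bins are
already on a common scale, so no per-column rescaling is applied. Covariance
versus correlation PCA was an open choice; covariance is used and recorded.
Component signs are fixed deterministically (the largest-magnitude loading of
each component is made positive) so results are reproducible across
platforms.

# Visual models

## Receptor sensitivities

Receptor spectral sensitivities are generated from the Govardovskii A1
visual-pigment alpha-band nomogram, parameterized only by the peak wavelength
`lambda_max` (`receptor_template()`). The bundled hawkmoth (*Manduca*-type)
trichromat uses the published peaks UV = 357, B = 450, G = 520 nm with
relative receptor densities 0.1 / 0.23 / 0.67. Fly sets carry the pale
(R7p/R8p) and yellow (R7y/R8y) ommatidial pairs with nomogram stand-in peaks
(330/460 and 350/530 nm); published fly curves are not tabulated in the
sources this follows, so measured curves can be supplied to `receptor_set()`
and the bundled defaults should be treated as documented stand-ins. Blowfly
and hoverfly share one code path and differ only in their receptor tables.

## Illuminants and quantum catches

Illuminants are relative photon-flux spectra; a utility converts energy-unit
tables (`energy_to_photon_flux()`), but it is off by default and the bundled
tables are treated as quantal. `"D65"` is a nominal CIE daylight table at
10-nm resolution; `"sunset"` is a *synthetic* low-colour-temperature stand-in
(2500 K blackbody photon flux, file `illum_sunset_synthetic.csv`) for the
reddish light at dusk when nocturnal hawkmoths begin foraging - measured
twilight spectra can be substituted by file path.

The raw catch of receptor *i* is the trapezoid-rule integral of reflectance
(as a proportion) x sensitivity x illuminant. Catches are von Kries adapted:
divided by the catch of the background (the mean leaf spectrum), so the
background maps to q = 1 in every receptor and any uniform rescaling of the
illuminant cancels. Grid-refinement tests confirm the integrals change by
< 0.1% when the wavelength step is halved.

## Hawkmoth: Maxwell triangle and receptor-noise-limited distances

Relative catches r (q normalized to sum 1) are projected into the Maxwell
triangle, `x = (r_G - r_UV)/sqrt(2)`, `y = sqrt(2/3) (r_B - (r_G + r_UV)/2)`;
the centre is the adaptation point and pure-receptor vertices lie at distance
sqrt(2/3). Chromatic discriminability uses the receptor-noise-limited (RNL)
model: contrasts are log catch ratios `df_i`, per-receptor noise is
`e_i = omega * sqrt(eta_max / eta_i)` from the densities ("neural" noise)
with Weber fraction omega = 0.1 in the most abundant (green) channel, giving
e = (0.2588, 0.1707, 0.1), and

```
dS = sqrt( (e1^2 (df3-df2)^2 + e2^2 (df3-df1)^2 + e3^2 (df2-df1)^2)
           / ((e1 e2)^2 + (e1 e3)^2 + (e2 e3)^2) )
```

in just-noticeable differences, with 1 JND the theoretical threshold.
Uniform scaling of all catches (a pure brightness change) cancels exactly.
Achromatic contrast is carried by the long-wavelength receptor; because the
downstream 0.1 discriminability convention is inconsistent with a 1-JND log
scale, the default form is Michelson, `|q_a - q_b| / (q_a + q_b)`, with the
log-JND form always available (`achromatic_contrast(..., form =
"log_jnd")`).

## Flies: categorical opponency

Fly colour vision is modeled categorically: opponent signals
`u = (q_R7p - q_R8p)/(q_R7p + q_R8p)` and `v` likewise for the yellow pair
define four quadrants - fly-UV (p+, y+), fly-blue (p-, y+), fly-yellow
(p-, y-), fly-purple (p+, y-). Loci within `1e-9` of an axis are labelled
`"boundary"` rather than silently assigned: the categorical model is
undefined at the adaptation point. Graded conspicuousness within the model is
the Euclidean distance in the (u, v) plane. Tetrachromatic RNL distances for
flies are deliberately out of scope.

# Discriminability statistics

Two procedures are implemented separately and reported side by side, because
the decision rule they support conflates them:

- `boot_group_distance()` resamples within groups and reports the mean and a
  percentile CI of the centroid-to-centroid distance. Centroids are taken in
  the metric's native space - log-catch space for RNL (so a centroid distance
  is itself a JND), the opponency plane for flies.
- `permutation_test()` shuffles group labels across all samples at the tested
  grouping level and reports `p = (1 + #(pseudo >= obs)) / (n_perm + 1)`;
  the add-one correction keeps p away from exactly 0. With small samples the
  observed partition is occasionally redrawn, so p can sit one or two counts
  above the floor - tests account for this. An `omnibus = TRUE` variant tests
  the mean distance over all group pairs at once, used where per-pair testing
  would invite multiplicity artifacts.

Seeds are mandatory arguments throughout; all Monte-Carlo output is
deterministic given the seed.

# Phylogenetic comparative methods

All tree-based likelihoods are computed in-package; trees are handled as
`ape::phylo` objects and `ape` supplies only infrastructure (Newick parsing,
shared-path matrices, matrix exponentials).

**Continuous traits** (`fit_continuous()`): the trait is multivariate normal
with mean `z0` and covariance `sigma2 * C`. `C_BM` is the shared-path matrix;
`C_OU = exp(-alpha d_ij) (1 - exp(-2 alpha t_a)) / (2 alpha)` (OU conditioned
on the root state, so alpha -> 0 recovers BM exactly - implemented with
`expm1` so the limit is numerically clean); `C_EB = (exp(r t_a) - 1)/r`. The
root and rate are profiled analytically, leaving a 1-D bounded quasi-Newton
optimization on log alpha (bounds 1e-8 to 1e3) or log |r| from five starts.
Models are compared by AICc with k = 2 (BM) or 3 (OU, EB). A zero-variance
trait returns a flagged degenerate fit rather than a spurious optimum.

**Ancestral states** (`anc_ml()`): joint ML states under BM satisfy an
inverse-branch-length weighted-average condition at every internal node - a
sparse linear system solved exactly. The root estimate coincides with the GLS
root, which the tests verify, and the whole solution is checked against
brute-force numeric likelihood maximization on small trees.

**Discrete traits** (`fit_mk()`): ER/SYM/ARD rate matrices fitted by
Felsenstein pruning with a uniform root prior (the root treatment was
unspecified; uniform is the neutral choice and is recorded in the fit).
Rather than the nonstandard "ANOVA among likelihoods" comparison,
`compare_mk()` runs likelihood-ratio tests against ARD plus AIC, and keeps
the fewest-parameter model not significantly worse - which reproduces the
usual outcome (ER preferred when data are sparse). Tips with unknown states
enter as marginalized (all-ones) partials.

**Stochastic mapping** (`stochastic_map()`): node states are drawn by
backward sampling from the pruning partials; branch histories conditional on
endpoints use rejection sampling with a retry cap (default 1000) and fall
back to exact uniformization (Poisson-number-of-jumps bridge), which keeps
short branches with forced changes robust. Node posteriors from 10,000 maps
match exactly enumerated marginals within 0.02 in the acceptance suite.

**Threshold model** (`threshold_mcmc()`): an ordered trait is a BM liability
cut at ordered thresholds, with rate 1 and first threshold 0 fixed for
identifiability and a uniform prior on the free thresholds scaled to tree
height (default 3x). Because every full conditional is available in closed
form - truncated normal at tips, normal at internal nodes, uniform for each
free threshold given the liabilities - the sampler is a pure Gibbs sampler.
(A design sketch proposed Metropolis proposals tuned to 20-40% acceptance;
Gibbs needs no tuning and mixes at least as well here, so that knob does not
exist.) A liability exactly at a threshold belongs to the upper category,
and every retained sample is constraint-checked in the tests.

**PGLS correlation** (`pgls_corr()`): the bivariate trait (environmental
liability, perceptual colour vector) is jointly ML-fitted with covariance
`R (x) C`; the evolutionary correlation is `r = R12 / sqrt(R11 R22)` and
`r = 0` is tested by a likelihood-ratio test against the diagonal-R model
(chi-squared, 1 df). Under BM on a star phylogeny this reduces exactly to the
Pearson correlation. The liability input is the posterior mean tip liability
from `threshold_mcmc()` (tip-only; whether ancestors entered the original
analysis is not determinable, and tip-only is the conservative default).
`color_vector()` builds the colour axis: PC1 of the species-by-receptor
catch matrix (hawkmoth) or of the species pairwise opponency-distance matrix
(fly).

# The synthetic world

`simulate_scenario()` generates the default test world once, with parameters
fixed by the study structure it emulates rather than by test outcomes:

- 11 species on a Yule tree rescaled to height 8 time units (the clade-age
  scale of a late-Miocene radiation), 4-11 individuals per species;
- the smaller root clade is white-flowered/hawkmoth-pollinated: logistic
  spectra rising near 420 nm from < 10% (UV-absorbing) to a plateau drawn
  from U(50, 80)% per individual; the larger clade is dark-flowered/
  fly-pollinated: flat spectra with maxima near 20%. All dark species share
  one template, mimicking the observed convergence of carrion-mimicking
  corollas; per-individual Gaussian noise (sd 1-1.5%) is the only
  within-species variation;
- leaves are chlorophyll-like Gaussians peaking at 550 nm and provide the
  adaptation background;
- ordered environmental zones come from thresholding a BM liability with
  clade offsets (white clade shifted toward zone 1, dark clade toward zones
  2-3), so habitat and pollination mode are phylogenetically linked, as in
  the real system.

What a green end-to-end test establishes: that white-vs-dark corollas
separate by more than 1 JND in hawkmoth space with the permutation p at its
floor, that dark species fall in a single fly quadrant (fly-UV against a
green-leaf background - the same quadrant reported for carrion-mimicking
flowers) with no significant within-quadrant discrimination, and that the
comparative machinery recovers simulated parameters. What it does *not*
establish: anything about real measurement artifacts (specular highlights,
instrument drift), about the adequacy of the nomogram stand-ins for true fly
sensitivities, or about the published study's numeric results, which depend
on externally deposited spectra.

Because the within-quadrant criterion is a null-hypothesis statement, its
permutation p is uniform under the generator: across arbitrary seeds it will
dip below 0.05 about 5% of the time. The test suite pins the documented
default seed (1); this is a property of testing a true null, not of the
implementation.

# Numerical choices and edge cases

- Trapezoid quadrature on the common grid for all catches.
- `expm1`-based OU/EB covariances keep the alpha, r -> 0 limits exact to
  the BM likelihood within 1e-4 (tested).
- Optimizers: L-BFGS-B on log parameters, five starts; Mk rates bounded in
  [1e-9, 1e3]; a rate pinned at a boundary with a single observed state is
  flagged degenerate instead of reported as an estimate.
- Truncated-normal sampling in the Gibbs sweep guards the far-tail case
  (interval probability below 1e-12) by clamping to the nearest feasible
  point.
- Permutation tests canonically sort samples by group label before applying
  the seeded permutation stream, so p-values are invariant to input order.
- PCA on fewer samples than bins is fine (prcomp); rank-0 input errors.

# Known limitations

- Fly receptor peaks and the sunset illuminant are stand-ins (clearly
  labelled); supply measured tables for fidelity.
- The threshold sampler keeps the liability rate fixed at 1; trees whose
  height is wildly out of scale with the category structure will mix slowly.
- PGLS assumes both traits share one phylogenetic correlation structure
  (common alpha under OU).
- The pipeline's fly-side PGLS uses the blowfly distance PCA only; hoverfly
  loci are computed but not separately carried into the comparative stage.
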