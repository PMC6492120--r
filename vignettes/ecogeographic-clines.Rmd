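---
title: "Models and methods: phylogenetic PLS, spatial clines, and isolation by distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: phylogenetic PLS, spatial clines, and isolation by distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoclines)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the parameters that
matter, what the synthetic-data generator does and does not emulate,
and the numerical decisions taken where the design was genuinely open.

## The data model

The package operates on two levels.

**Between species.** Each of n species contributes a p-vector of
log-scale morphometric means, a q-vector of environmental variables,
a (latitude, longitude) range centroid, and a tip on a rooted,
time-scaled phylogeny. Species means are formed as the arithmetic mean
of the female mean and the male mean per trait (`species_means()`),
not the pooled specimen mean: pooling would let the better-sampled sex
drag the species value, while the sex-mean average is balanced by
construction. Morphology enters on the natural-log scale, where ratios
of linear measurements become additive contrasts and a common size
factor appears as a positive loading on everything. The environment
block mixes units (degrees Celsius, millimetres of rain, index codes),
so it is scaled to unit variance (`scale_unit_variance()`); the
morphology block is deliberately **not** scaled, so that the shared
allometric size factor can dominate the first latent variable rather
than being flattened away.

**Within species.** Specimens carry sex, locality and possibly damaged
(missing) measurements. Sexual dimorphism is removed by centering each
specimen on its (species, sex) mean (`remove_sex_effects()`); the
output is a deviation (specimen minus mean). The mirror convention
(mean minus specimen) differs only in sign, which no downstream
covariance or SVD can see; deviations are the convention every later
stage assumes. Missing cells are completed by `em_impute()` *after*
sex centering and within species, because the multivariate-normal
model underlying EM is a within-group model; between-species analyses
instead require complete species-sex-trait cells.

## Brownian motion and GLS whitening

Species values are not independent draws: under Brownian motion on
the phylogeny, the covariance between two species is proportional to
the branch length they share from the root to their most recent
common ancestor. `tree_to_covariance()` builds this n × n matrix C
(diagonal: root-to-tip depth). All phylogenetic fits reduce to one
primitive, `gls_whiten()`:

\[ \tilde X = L^{-1} (X - \mathbf{1} a^\top), \qquad L L^\top = C, \quad
   a = (\mathbf{1}^\top C^{-1}\mathbf{1})^{-1} \mathbf{1}^\top C^{-1} X . \]

Whitened blocks have ordinary cross-products equal to the GLS
cross-products of the raw data, so the downstream SVD machinery is
identical for ordinary and phylogenetic runs — the ordinary path just
uses column centering instead. Two consequences are used as master
checks throughout the test suite: an equal-branch star phylogeny makes
every phylogenetic result collapse onto its ordinary counterpart, and
globally rescaling all branch lengths leaves every loading unchanged
(only the singular values rescale).

Numerics: Cholesky factorization with a diagonal jitter of
`1e-10 × mean(diag(C))`, escalated a hundredfold a few times before
giving up, handles trees with effectively zero internal branches.
Covariances use the n − 1 denominator everywhere in the between-unit
analyses, so the star-tree equivalence is exact rather than
asymptotic.

## Two-block PLS

`fit_2bpls()` decomposes the (whitened) cross-covariance
`R = X̃ᵀỸ/(n−1)` by SVD. The loading pairs successively maximize score
covariance, the singular values *are* those covariances, and
`d_k²/Σd_i²` is the per-dimension share of squared covariance — the
quantity a scree plot shows. Per-dimension score correlations are
computed from whitened scores without re-centering (whitening already
removed the GLS mean); in the ordinary case this is exactly the
Pearson correlation. In phylogenetic fits the raw-centered projections
are additionally reported (`scores_*_raw`) for plotting, since
whitened scores live in a rotated coordinate system.

Degenerate input (an exactly zero R) yields zero singular values and
canonical basis loadings with a warning rather than an error, so
pipelines can proceed. SVD sign indeterminacy is resolved by flipping
each morphology loading so its largest-magnitude entry is positive,
with the paired vector flipped jointly; ties break to the first index.

`pls_permutation_test()` permutes rows of the whitened second block —
after whitening the rows are exchangeable under the null, which is the
point of permuting on that side of the transform — and supports both
`d1` and `r1` as statistics, since small within-species studies report
correlation-based p-values while the covariance is the quantity PLS
maximizes. The p-value is `(count ≥ observed + 1)/(n_perm + 1)`; when
n! ≤ n_perm the test switches to exact enumeration of all n!
permutations (p = count/n!, identity included), so tiny-n calls do not
pretend to Monte-Carlo resolution they cannot have.

## Reduced-rank regression for spatial clines

A cline is a slope over geography, not a covariance with it. For each
trait, `pgls_coefficients()` fits `trait ~ intercept + latitude +
longitude` (OLS, or GLS through the same whitening); `fit_rrr()` then
decomposes the p × 2 coefficient matrix `B = U D Wᵀ`. For any unit
trait combination u, the fitted surface's gradient norm is ‖Bᵀu‖ ≤ d₁,
with equality at u₁ — so d₁ is the steepest slope any trait
combination attains, w₁ its compass direction in (lat, lon) space.
This is the package's answer to why not simply run PLS on (X, G): PLS
finds the direction of maximal covariance, which an elongated sampling
range dominates regardless of where the cline is steep. A dedicated
test plants a cline perpendicular to a 10:1 elongated range and
asserts that RRR recovers the cline while PLS aligns with the long
axis.

Coordinates are used in raw decimal degrees with no projection and no
cos-latitude correction of longitude: the singular values are then
interpretable as trait-log-units per degree, matching how range
centroids and specimen localities are recorded. The anisotropy of a
longitude degree (it shrinks with latitude) is a known limitation; at
the within-species scales simulated here (~30° boxes in the tropics
and subtropics) it distorts directions by a few degrees at most, and
any fixed projection would trade that for a different distortion.
Rotation equivariance (rotating the coordinate frame rotates w and
leaves d alone) is tested explicitly.

## EM imputation

`em_impute()` is the standard multivariate-normal EM: E-step, replace
each row's missing cells by their conditional expectation given that
row's observed cells under the current (μ, Σ); M-step, re-estimate μ
and Σ from the completed matrix plus the conditional-covariance
correction term, with the maximum-likelihood denominator 1/n.
Defaults: `tol = 1e-6` on the largest change of any imputed value,
`max_iter = 100`, ridge `1e-6 × mean(diag(Σ))` added whenever p ≥ n or
Σ is numerically singular. The ridge matters: within-species
craniodental blocks typically have more traits than specimens, where
unregularized Σ cannot be inverted. Non-convergence sets a flag
instead of raising, because a partially converged completion is still
the best available estimate; observed cells are never altered by
construction. Ignorability (missing completely at random) is assumed —
which is exactly what the generator plants, and the reason the
generator offers nothing else.

## Isolation by distance

`geodesic_distance_matrix()` uses the haversine formula on a sphere of
radius 6371.0088 km (the mean Earth radius); the sub-half-percent
error against an ellipsoid is immaterial for a permutation test that
only consumes the relative configuration of distances.
`mantel_test()` correlates upper triangles and permutes rows and
columns of the second matrix jointly; the p-value is one-sided for
positive association, because isolation by distance is a directional
hypothesis (dissimilarity growing with distance). Specimens sharing a
locality keep distance zero — no jitter — since duplicate localities
are real features of museum samples.

## What the generator emulates, and what it does not

`sim_config()` + `simulate_ecogeo_study()` produce: a unit-depth
pure-birth tree (`simulate_yule_tree()`), species blocks drawn matrix-
normally with row covariance C and column covariance
`Σ = σ²I + rank-1 coupling c·u*v*ᵀ` (PSD exactly when c ≤ σ²,
`build_joint_covariance()` refuses anything larger), uniform range
centroids, and specimens equal to species mean + male sex effect +
planted cline along a chosen trait direction + optional spatially
correlated drift field (exponential covariance in geodesic distance)
+ independent noise, with MCAR deletions. Defaults are chosen to mimic
a genus-level craniodental study at reduced dimension: a dozen
species, unit tree depth, coupling at 0.9 of the Brownian rate, six
specimens of alternating sex per species, individual noise an order of
magnitude below the between-species scale, and a tropical ~30°
bounding box.

Simulated trait values are analysis-scale (they may be negative), so
the strict-positivity invariant of raw millimetre tables is relaxed
for synthetic tables; feed them to downstream steps with
`on_log_scale = FALSE`.

What passing tests on these data show: the estimators recover planted
low-rank structure, hold their nominal size, and respect their
algebraic identities. What they do not show: robustness to
non-Brownian evolution (Ornstein–Uhlenbeck pull, rate shifts),
measurement error, non-MCAR damage (a broken zygomatic is not random
with respect to size), discrete or bounded environmental codes, or
real spatial sampling designs — museum localities are anything but
uniform.

## Validation sizes and thresholds

The validation suite runs at deliberately modest sizes chosen to make
the Monte-Carlo answers sharp without being wasteful: maximality of
the SVD solutions is checked against 10,000 random unit loading pairs;
coupling recovery uses 200 replicates at n = 32 species, p = 6, q = 4,
c = 0.9σ²; permutation-test size uses 500 null replicates at 199
permutations each (199 keeps the test exact at the 0.05 level while
500 replicates give a ±2% standard error); Mantel power uses 200
replicates at 40 localities. One honest caveat established with a
20,000-replicate side experiment: at n = 32 the sampling noise of a
6 × 4 cross-covariance puts the *true* median alignment of the first
recovered axis with the planted one at about 0.896, so a ≥ 0.9
recovery check at exactly these conditions sits marginally beyond what
the estimator can deliver and will read as a near-miss rather than a
failure of the method.

## Known limitations

Beyond the generator gaps above: no Ornstein–Uhlenbeck or
branch-length transforms (λ, κ, δ); no ancestral-state reconstruction;
no partial Mantel tests or spatial autocorrelograms; no more-than-two-
block PLS; no predictive PLS regression; no map projections or
raster climate extraction — environmental values are consumed as
tables, which is a data contract, not an analysis step.
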