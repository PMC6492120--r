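# ecoclines

Multivariate ecogeography for morphometric data: how does a block of
craniodental (or any linear) measurements covary with climate and
ecology across related species, how steep is its spatial cline over
latitude and longitude, and does within-species variation carry a
signature of isolation by distance? `ecoclines` implements the full
analysis chain for these questions, with and without phylogenetic
correction, plus a synthetic-data generator with planted ground truth
so every stage can be validated.

## Methods at a glance

* **Two-block partial least squares (2B-PLS).** With a centered
  morphology block `X` (n × p, natural-log scale) and environment
  block `Y` (n × q, unit-variance scaled), the cross-covariance
  `R = XᵀY/(n−1)` is decomposed by SVD, `R = U D Vᵀ`. Each singular
  value `d_k` is the covariance of the paired latent-variable scores
  `Xu_k`, `Yv_k`; `d_k²/Σd_i²` is the fraction of squared covariance
  carried by dimension k.
* **Phylogenetic variants.** Species are not independent: under
  Brownian motion on a time-scaled tree their covariance is the shared
  root-to-ancestor path length matrix `C`. Both blocks are GLS-whitened
  (`L⁻¹(X − 1aᵀ)` with `LLᵀ = C` and `a` the GLS mean) before the same
  decomposition — ordinary cross-products of whitened data equal the
  GLS cross-products of raw data. With an equal-branch star phylogeny
  the phylogenetic fits collapse exactly onto the ordinary ones.
* **Reduced-rank regression (RRR) for spatial clines.** Each trait is
  regressed on latitude and longitude; the SVD of the resulting p × 2
  coefficient matrix `B = U D Wᵀ` gives the maximal slopes `d_k`
  (trait-log-units per degree), the morphological loadings `u_k`, and
  the unit geographic gradient directions `w_k`. Unlike a PLS of traits
  against coordinates, this is not dragged toward the long axis of an
  elongated sampling range.
* **EM imputation.** Damaged specimens are completed by
  expectation–maximization under a multivariate normal, imputing each
  missing cell by its conditional expectation given the observed cells,
  with ridge regularization when traits outnumber specimens.
* **Mantel tests.** Isolation by distance is tested by correlating
  geodesic (haversine, r = 6371.0088 km) and Euclidean phenotypic
  distance matrices with a joint row/column permutation null
  (10,000 permutations by default).

## Worked example

```r
library(ecoclines)

study <- simulate_ecogeo_study(sim_config(n_species = 12, p = 8, q = 6,
                                          coupling_strength = 0.9, seed = 7))
ds <- study$dataset                       # aligned X, Y, G + tree
C  <- tree_to_covariance(ds$tree, ds$species)
fit_phy <- fit_2bpls(ds$X, scale_unit_variance(ds$Y), C)
fit_phy
#> phylogenetic two-block PLS: n=12, 6 dimensions
#>        d effect_pct      r
#> 1 2.7236    57.9414 0.8785
#> 2 1.4822    17.1601 0.7734
#> 3 1.3125    13.4560 0.7563
#> ...
```

The first latent variable carries 58% of the squared covariance
between blocks, with a block correlation of 0.88 — the planted rank-1
coupling surfacing as the dominant shared axis (at n = 12 species the
loading estimate is noisy; at the generator's validation size, n = 32,
the recovered axis aligns with the planted one at median |cos| ≈ 0.89).

```r
rr <- fit_rrr(ds$X, ds$G, C)
rr
#> phylogenetic reduced-rank regression: n=12 traits p=8
#>    slope effect_pct      r
#> 1 0.0521      85.17 0.7626
#> 2 0.0217      14.83 0.7738
```

The steepest multivariate cline runs at 0.052 trait-log-units per
degree along the direction `rr$w[, 1]`, and carries 85% of the total
squared slope.

```r
loc <- simulate_ibd_localities(m = 40, ibd_strength = 1, seed = 3)
mantel_test(geodesic_distance_matrix(loc$coords),
            phenotype_distance_matrix(loc$X), n_perm = 999, seed = 4)
#> Mantel test: r = 0.3791, p = 0.001 (999 permutations, n = 40)
```

A planted isolation-by-distance field is detected at the smallest
attainable p-value.

A YAML-driven command line (`simulate`, `preprocess`, `pls`, `rrr`,
`mantel`) lives at `inst/cli/ecoclines.R`; see the methods vignette
(`vignettes/ecogeographic-clines.Rmd`) for the models, assumptions
and numerical choices.

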