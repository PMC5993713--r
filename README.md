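# macroniche

Why do some clades hold a hundred species and their sisters only two? One
recurring answer is climate: lineages that readily shift the set of
temperature and precipitation conditions they occupy may speciate faster
than lineages whose climatic niches are conserved. `macroniche` is an R
package for testing that idea at the clade level. It links, across families
(or any set of clades on a dated tree), net diversification rates and
species richness to the structure of climatic niches: how wide the clade's
niche is, how wide its species' niches are, how much the species' niches
diverge from one another, how fast the niche evolves, where the niche sits
(tropical vs. temperate), and how large the clade's range is.

The package is aimed at phylogenetic comparative biologists. It contains the
full estimation and inference machinery plus a synthetic-data generator with
known ground truth, so the entire pipeline is testable end to end without
any external data.

## The quantities and models

With six bioclim variables (BIO1, BIO5, BIO6, BIO12, BIO16, BIO17) on an
occupancy grid:

* **Niche width.** For entity *i* (species or family = union of its species'
  cells), the raw range on variable *v* is `Rg_iv = max − min` over occupied
  cells. Ranges are standardized against the pool of all species,
  `StRg_i = (Rg_i − min Rg) / (max Rg − min Rg)`, and the overall niche
  width is the product of the six standardized ranges. Niche position is the
  per-variable mean over occupied cells; geographic extent is the summed
  cell area of the union range.
* **Net diversification rate.** The stem-age method-of-moments estimator
  `r̂_ε = ln[n(1−ε) + ε] / t` from richness *n* and stem age *t* (Myr), at
  relative extinction fractions ε ∈ {0, 0.45, 0.9}; ε = 0.45 is the
  headline value.
* **Rate of niche evolution.** The maximum-likelihood Brownian-motion rate
  σ² of the species means of BIO1 and BIO12 on each within-family tree;
  a Pagel's-λ variant (`lambda_model_fit()`) is available for families with
  ≥ 3 species.
* **Niche divergence (ND).** The residual of the PGLS regression
  `ln(family niche width) ~ ln(mean species niche width)`: under perfect
  within-family niche conservatism the two widths coincide and ND ≈ 0;
  positive ND means the member species tile little-overlapping climates.
* **PGLS.** Generalized least squares whose error covariance is the Pagel-λ
  transform of the phylogenetic covariance, with λ estimated by profile
  maximum likelihood on [0, 1] (κ = δ = 1). r² is computed in the whitened
  space against the GLS intercept-only fit.
* **Variance partitioning.** Commonality analysis over the four predictor
  blocks — family niche width (NW), geographic extent (GE), niche
  divergence (ND) and the two niche-evolution rates (NE) — via
  inclusion–exclusion over all 15 block-subset PGLS fits; the components
  sum to the full-model r² identically.
* **Null models.** 1000 resampled sets of null families (same richness,
  species drawn with replacement from an unconstrained, spatially
  constrained, or climatically constrained pool) give add-one empirical
  p-values for the observed r² of the width/divergence regressions.
* **Clade robustness.** The species tree is sliced into disjoint clades
  whose stem age is the smallest value at or above a target age (e.g. the
  mean family stem age), and the analysis is repeated with ln richness as
  the response.

## Worked example

Simulate the default divergence-driven scenario (92 families, mean stem age
41.65 Myr, niche-evolution rates coupled to diversification) and run the
full analysis:

```r
library(macroniche)

sc <- simulate_scenario(scenario_config(seed = 1))
pl <- run_pipeline(sc)
print(pl$family_table)
print(pl$suite)
print(pl$varpart)
```

```
family_table: 92 analysis families, 1546 species; 0 excluded
Univariate PGLS suite (response: rate_eps0.45)
            model             predictors      r2      F df1 df2        p lambda  slope   ci95
        family_nw                  ln_nw 0.45200  74.20   1  90 2.19e-13  0.999 0.1970 0.0455
  mean_species_nw                ln_msnw 0.00464   0.42   1  90 5.19e-01  0.966 0.0202 0.0619
 niche_divergence                     nd 0.61600 144.00   1  90 2.17e-20  0.882 0.3420 0.0566
           extent              ln_extent 0.26000  31.70   1  90 2.03e-07  0.979 0.3460 0.1220
   temp_evol_rate             ln_s2_bio1 0.70600 216.00   1  90 1.22e-25  0.000 0.4340 0.0587
 precip_evol_rate            ln_s2_bio12 0.63300 155.00   1  90 2.80e-21  0.618 0.3410 0.0544
  niche_evol_both ln_s2_bio1+ln_s2_bio12 0.78900 167.00   2  89 7.91e-31  0.347     NA     NA
 nd_vs_evol_rates ln_s2_bio1+ln_s2_bio12 0.55500  55.50   2  89 2.21e-16  0.000     NA     NA
   niche_position                        0.00000     NA   0  91       NA  0.964     NA     NA
         richness                   ln_n 0.56100 115.00   1  90 8.67e-18  1.000 0.5960 0.1100
Variance partitioning: full-model r2 = 0.8525
Unique contributions:
    NW     GE     ND     NE
0.0029 0.0076 0.0147 0.1956
Total shared: 0.6316 (components sum to 0.852459)
```

Reading the table: each row is one univariate (or small multivariate) PGLS
of ln diversification rate (ε = 0.45) across the 92 families. In this
divergence-driven world, niche divergence (r² = 0.62) and the
niche-evolution rates (bivariate r² = 0.79) dominate; family niche width
(0.45) and geographic extent (0.26) trail them; mean species niche width
explains essentially nothing (0.005), and no niche-position variable enters
the stepwise model. Diversification rates in turn carry the richness signal
(r² = 0.56). The variance partitioning shows that most of the explained
variance is shared between divergence and the evolution rates — as expected
when both measure the same underlying niche lability.

Null models and the fixed-age clade slicing are available through
`null_model()` and `clade_robustness()`, or via
`run_pipeline(sc, null_reps = 1000, robustness = TRUE)`.

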