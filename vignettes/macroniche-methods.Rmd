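---
title: "Methods: climatic niche structure and clade diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climatic niche structure and clade diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macroniche)
```

`macroniche` implements a comparative analysis that asks how much of the
variation in net diversification rate (and species richness) among clades
is explained by the structure of their climatic niches. This vignette is
the package's own account of the models, the choices behind them, and what
the synthetic-data validation does and does not establish.

## 1. Quantities

### Niche widths, positions, extents

Climate is summarized by six bioclim variables: annual mean temperature
(BIO1, °C), maximum temperature of the warmest month (BIO5), minimum
temperature of the coldest month (BIO6), annual precipitation (BIO12, mm),
and precipitation of the wettest (BIO16) and driest (BIO17) quarters. An
entity's niche on variable $v$ is described by the minimum, maximum and
mean over its occupied grid cells; the raw niche width is
$Rg_v = \max - \min$. To combine variables in different units, raw widths
are rescaled against the pool of all $j$ species,

$$\mathrm{StRg}_i = \frac{Rg_i - \min(Rg_1{:}Rg_j)}
                         {\max(Rg_1{:}Rg_j) - \min(Rg_1{:}Rg_j)},$$

and the overall niche width is the product of the six standardized widths.
A family's niche is computed by the same protocol over the union of its
member species' cells; its niche position is the per-variable mean over the
union, and its geographic extent the summed area of the union cells.

**Standardization pool.** Species widths are standardized against the
species pool. For family widths we also standardize against the *species*
pool rather than against the families themselves. This is a deliberate
design choice: rescaling any finite pool against itself forces at least one
entity per variable to standardized width exactly 0, so one family per
variable would have an overall width of 0 and an undefined ln-transform —
the pipeline could never run. Standardizing family raw ranges against the
species pool applies the same rescaling constants at both levels, keeps
every family width strictly positive (families are unions of ≥ 2
distinct-ranged species), and allows family widths slightly above 1, which
is harmless under the ln-transform. The pool choice is an explicit argument
of `standardize_widths()` and `family_niche()` and is recorded in the
family table's metadata. Species with standardized width 0 (the pool
minimum) are retained: species widths enter the analysis only through the
family mean, which stays positive.

An alternative two-axis width (`pca_family_width()`) projects union cells
onto the first two principal axes of the standardized all-cell climate
matrix and multiplies the two axis ranges; on the synthetic grids it
rank-correlates strongly with the product width.

### Net diversification rates

The stem-age method-of-moments estimator
$\hat r_\varepsilon = \ln[n(1-\varepsilon) + \varepsilon]/t$ converts a
clade's extant richness $n$ and stem age $t$ (Myr) into a net rate per
lineage per Myr under an assumed relative extinction fraction
$\varepsilon$ (extinction/speciation). The conventional grid
$\varepsilon \in \{0, 0.45, 0.9\}$ is computed throughout; 0.45 is the
headline value and the others are emitted alongside. The estimator is exact
through the mean of a pure-birth process ($\ln E[n] = rt$); note that the
*median* richness of a pure-birth clade is below its mean, so median-based
recovery of a known rate is biased low by roughly $\ln(1/\ln 2)/t$ and only
approaches the truth for $rt \gtrsim 4$.

### Rates of niche evolution

The per-family rate of niche evolution is the ML Brownian-motion variance
$\hat\sigma^2$ of the species means of BIO1 (temperature niche rate) and
BIO12 (precipitation niche rate) on the family's subtree:
$\hat\mu = (\mathbf 1' C^{-1} x)/(\mathbf 1' C^{-1}\mathbf 1)$ and
$\hat\sigma^2 = (x-\hat\mu\mathbf 1)' C^{-1} (x-\hat\mu\mathbf 1)/N$, with
$C$ the phylogenetic covariance. We use ML (divide by $N$), the standard
comparative-methods default, so the $(N{-}1)/N$ downward bias is expected
and visible in recovery tests; for two-species families the bias is a
factor of 2 and, on the log scale, roughly $-2$ — a point that matters for
interpretation (Section 4). A Pagel's-λ model (`lambda_model_fit()`,
bounded profile search on $[0,1]$, tolerance $10^{-8}$, 21-point grid
pre-scan) is provided for families with at least three species; λ = 1
recovers the BM fit exactly. Families that are monospecific in the tree,
not monophyletic on their sampled tips, or absent are excluded with logged
reason codes; exclusions are applied to the analysis tree, not the
membership table.

### Niche divergence

Divergence of the member species' niches within a family is measured as the
raw residual of the PGLS regression
$\ln(\text{family width}) \sim \ln(\text{mean species width})$. With
perfect within-family conservatism the family width equals the species
widths and the residual is ~0; species tiling disjoint climates push the
family width far above the mean species width and give a large positive
residual.

## 2. Regression machinery

`pgls_fit()` implements generalized least squares with error covariance
$V(\lambda) = \lambda C + (1-\lambda)\,\mathrm{diag}(C)$ (off-diagonals
multiplied by λ; κ and δ fixed at 1). λ is estimated by profile maximum
likelihood of the residual model on $[0,1]$ — a 21-point grid pre-scan
against local optima, then golden-section refinement to $10^{-8}$. On an
ultrametric tree every $V(\lambda)$ is diagonal in the eigenbasis of $C$,
so the covariance is decomposed once per tree (`pgls_context()`) and each λ
evaluation is a diagonal rescaling; this is what makes 1000-replicate null
models cheap. $r^2 = 1 - RSS/TSS$ is computed in the whitened space against
the GLS intercept-only fit *under the same λ*, keeping it in $[0,1]$; F, p
and t-based 95% slope intervals follow standard GLS theory with
$df = (k-1,\, n-k)$. λ = 0 reproduces OLS to machine precision and fixed-λ
fits agree with `nlme::gls` + `ape::corPagel` to $10^{-10}$ (tested).

Forward stepwise selection (used for the six niche-position variables) adds
the candidate with the largest partial F while its entry p-value is below
`alpha_enter = 0.05` — a value we chose and record in the output, as there
is no canonical default. The partial F compares the candidate model (λ
re-estimated) with the current model refitted at the candidate's λ, in the
same whitened space; rank-deficient additions get F = 0.

Variance partitioning fits all $2^4-1$ subsets of the blocks NW
(ln family width), GE (ln extent), ND (divergence, untransformed) and NE
(ln temperature + ln precipitation rates as one block) and forms
commonality coefficients by inclusion–exclusion,
$C(S) = -\sum_{T\subseteq S} (-1)^{|T|}\, r^2(T \cup S^c)$. The 15
components sum to the full-model $r^2$ identically (the sum telescopes
whatever the subset values are), which the tests assert to $10^{-10}$.
Because each subset re-estimates its own λ, "zero" components are zero only
up to small λ-profile differences, and negative commonalities (suppression)
can occur and are reported as computed. All variables except niche
divergence and niche position are ln-transformed by the caller; the engine
itself never transforms.

**Conventions recorded, not derived:** univariate p-values are reported
unadjusted for multiplicity; slope intervals are t-based rather than
normal; both one-tailed empirical p-values are reported for null models.

## 3. Null models and clade slicing

Null families keep the observed family tree, richness and diversification
rates; only the niche side is resampled. Per replicate, each family draws
its $n$ species with replacement from (1) all species, (2) species whose
range centroid lies in the family's longitude/latitude bounding box, or
(3) species whose six per-variable means all lie inside the family's
min–max climate envelope — the simplest faithful readings of "spatially"
and "climatically" constrained pools, recorded in the output. Null family
widths are rebuilt from member min/max extremes against the species pool,
mean species widths from member widths, and null divergence from a fresh
PGLS per replicate. Empirical p-values use the add-one estimator
$p = (\#\{r^2_{null} \ge r^2_{obs}\} + 1)/(R+1)$ (upper tail; mirrored
lower tail), so $p \ge 1/(R+1) > 0$ always. A resampled family that lands
on a zero width (possible when a single pool-minimum species is drawn
repeatedly) is redrawn and counted; an empty constrained pool falls back to
the unconstrained pool with a logged warning.

The fixed-age robustness variant (`clade_robustness()`) cuts the master
species tree at a target age: along each root-to-tip path it selects the
clade whose stem age is the smallest value still at or above the target
(ties between nested clades, which require zero-length branches, resolve to
the larger clade). The selected clades are provably disjoint and cover all
tips. Monospecific clades are excluded with logged reasons, and the full
regression panel and variance partitioning are rerun with ln clade richness
as the response.

## 4. The synthetic generator: what it emulates, what it does not

`simulate_scenario()` builds a world in which the ground truth is known:

* a 60 × 120 equal-area climate grid with a latitudinal temperature
  gradient (27 °C down to −8 °C), a longitudinal precipitation gradient
  (3000 mm down to 100 mm), cell noise (sd 0.8 °C / 60 mm), and
  seasonal/quarter offsets that guarantee BIO5 ≥ BIO1 ≥ BIO6 and
  BIO12 ≥ BIO16 ≥ BIO17 ≥ 0 in every cell;
* a dated family tree of 92 families rescaled to a mean stem age of
  41.65 Myr, with every internal node pushed back by `min_stem_age = 8`
  Myr so that no family has a vanishing stem age (a stem age near zero
  would make its rate estimate an unbounded leverage point; the youngest
  real mammalian family stems are of this order);
* per-family expected-richness targets drawn log-normally
  (`richness_meanlog = log 12`, sd 0.9, window 2–150), converted to true
  net rates $r_f = \ln(E\,n_f)/t_f$ — exact for pure birth — and realized
  as forward-simulated pure-birth species trees conditioned on the window
  (out-of-window draws redrawn and counted);
* species niche positions (target BIO1 and BIO12) evolving by Brownian
  motion at the family's true rate $\sigma^2_f$ on each within-family tree,
  with the stem edge included; under the default `"h2"` coupling
  $\sigma^2_f \propto r_f^2$ up to log-normal noise (divergence-driven
  speciation), `"decoupled"` severs the link, `"h0"` fixes $\sigma^2$
  across families;
* ranges as connected climate-envelope cell sets around each species'
  niche position, with log-normal widths (≈ 3 °C × 400 mm) scaled by a
  family-level effect (log-sd 0.6) that is independent of diversification —
  this is what makes mean species width vary across families while carrying
  no rate signal. Envelopes are widened until they hold ≥ 2 cells; member
  cell sets within a family are forced to be pairwise distinct, and a
  global pass widens any family whose union range would sit exactly at the
  species-pool minimum — both guards exist because identical or
  pool-minimum ranges would produce exactly constant traits or zero widths,
  which the pipeline treats as hard errors.

Every stage derives its own sub-seed from the scenario seed, so each stage
is independently reproducible and a fixed seed reproduces the dataset
byte-for-byte.

**What passing tests show — and what they do not.** The generator gives
analytic control over widths and divergence, which is exactly what the
recovery tests need; it does not emulate real biogeography. Three caveats
follow.

1. *Ranges are climate-defined.* Because a species' range is its climate
   envelope, a family's spatial bounding box carries the same information
   as its climate envelope. Spatially constrained null pools therefore
   preserve each family's climatic spread, and constrained null
   divergence–rate $r^2$ tends to sit *above* the unconstrained one here —
   with real geography (topography, dispersal barriers, historical
   contingency) the two constraints are not equivalent and the contrast
   can go the other way. The tests assert the validity, determinism and
   calibration of the null machinery, not the direction of that contrast.
2. *"Decoupled" truth does not mean flat estimates.* Even when true
   $\sigma^2_f$ is independent of $r_f$, two estimator-level couplings
   remain: realized family divergence grows with richness by sampling
   alone (the very effect the null models are built to quantify), and ML
   $\hat\sigma^2$ is biased low by $(N{-}1)/N$, which on the log scale is
   large for two-species families — so estimated niche-evolution rates
   correlate with richness, and richness sits in the rate estimator's
   numerator. Regressions of the rate on *estimated* divergence or
   $\hat\sigma^2$ in the decoupled scenario are therefore not expected to
   have uniform p-values, and the tests instead verify that the generator's
   truth is decoupled and that PGLS is type-I calibrated against genuinely
   independent predictors. The same couplings exist in any real-data
   analysis that uses these estimators on small families.
3. *Scale.* Test and validation runs use scaled-down designs chosen for
   thoroughness per unit time: e.g. 25–40 families for pipeline tests,
   99–500 null replicates in calibration experiments, 200 replicates for
   slope-recovery checks. The defaults of the generator itself (92
   families, 1000 null replicates) remain the study conditions.

## 5. Numerical choices and degenerate inputs

* λ searches: 21-point grid + `optimize()` (tolerance $10^{-8}$); boundary
  ties resolve to the boundary value.
* Perfect fits (RSS ≈ 0) short-circuit the λ profile and report $r^2 = 1$,
  F = ∞, p = 0.
* Covariance factorizations use Cholesky (non-ultrametric) or a single
  symmetric eigendecomposition (ultrametric); eigenvalues below
  $10^{-12}\,h$ mark the transform degenerate at that λ.
* Constant traits return $\sigma^2 = 0$ with a warning from
  `bm_sigma2_ml()`; the table builder refuses them (ln undefined), as it
  refuses zero niche widths and missing values, listing the offending
  families.
* Non-ultrametric trees are accepted for covariance construction and PGLS
  but rejected by `stem_age()` and `slice_clades_by_stem_age()` with a
  clear error; polytomies are accepted as-is and never randomly resolved.
* Monophyly is tested on the sampled tips only; how partial sampling should
  interact with paraphyly is genuinely underdetermined, and this is the
  most conservative testable reading.

## 6. Known limitations

The estimators assume the supplied tree and dates are correct; errors in
stem ages propagate directly into rates. The product-of-widths measure
treats the six variables symmetrically and ignores their correlation
(the PCA width is the cross-check). Niche positions are unweighted means
over union cells, not species-weighted. The null models resample species
as exchangeable units — range sizes and within-family spatial structure are
preserved only through the constrained pools. None of the analyses
separate speciation from extinction; the net-rate estimator cannot, by
construction.
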