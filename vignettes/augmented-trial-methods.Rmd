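---
title: "Methods: augmented-design adjustment, genetic parameters, and the synthetic panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: augmented-design adjustment, genetic parameters, and the synthetic panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(augtrial)
```

## The design and its model

An augmented block design screens a large collection of unreplicated
*test* entries by embedding a few replicated *check* varieties in every
block. The working model for a plot value is

$$y = \mu + \beta_j + \gamma_g + \varepsilon,$$

with block effects $\beta_j$ and genotype effects $\gamma_g$. Because
each test occurs once, only the checks inform $\beta_j$. The package uses
Federer's classical estimator: the adjustment of block $j$ is its check
mean minus the unweighted grand mean of block check means, and the
adjusted test value is the observation minus its block's adjustment.
Check entries are reported as raw means over blocks. On complete designs
this reproduces the least-squares genotype BLUEs exactly — the test suite
asserts that equivalence against an explicit normal-equations solve. We
deliberately do not shrink toward a mixed-model BLUP; that is a different
estimator with different reporting conventions and is out of scope.

A check missing from a block degrades that block's adjustment (it is
computed from the remaining checks, with a warning) rather than aborting:
real trials lose plots, and a screening pipeline that dies on one lost
check plot is useless. A block with *no* checks gets adjustment zero.

### ANOVA conventions

Per location we report a sequential (type-I) decomposition in the
classical augmented order — Block (unadjusted), then the genotype factor
expanded hierarchically into Tests-vs-Checks (1 df), Checks ($c-1$) and
Tests ($t-1$) — so the three genotype components are additive by
construction, and the intra-block error carries $(c-1)(b-1)$ df from the
checks-by-blocks subtable. The model fits are delegated to `stats::lm`;
the arithmetic identities (additivity, df bookkeeping, shift invariance)
are what the package owns and tests.

The combined analysis is a two-way decomposition of the genotype ×
location table of adjusted test means, one value per cell. Checks are
excluded: the across-location analysis this mirrors carries $t-1$
genotype df, i.e. tests only. Two consequences are worth stating plainly:

* With a single adjusted mean per cell, G×E cannot be separated from
  error internally. Genotype and Environment are tested against the G×E
  mean square; when per-location tables are supplied, G×E is tested
  against their pooled intra-block error with the effective replication
  of an adjusted mean taken as 1. This choice is recorded in the output
  metadata because the source convention is not stated anywhere
  authoritative.
* Genotypes missing at any location are dropped (with a warning), the
  same reduction a real panel undergoes when, e.g., nutrient assays cover
  only a subset.

## Genetic parameters

With $n_e$ environments, the method-of-moments mapping is
$\sigma^2_g = (MS_G - MS_{G\times E})/n_e$, $\sigma^2_e = MS_{G\times E}$
and $\sigma^2_p = \sigma^2_g + \sigma^2_e$. We chose this two-component
bookkeeping because published component tables for this class of analysis
satisfy $PV = GV + EV$ exactly row by row; a separate G×E component would
break that identity. Negative $\sigma^2_g$ estimates truncate to zero
with a flag — they are sampling noise, not errors. Downstream statistics
(`coefficients_of_variation`, `broad_sense_heritability`,
`genetic_advance`) accept components directly, so published component
tables can be re-analysed without the ANOVA stage; this decoupling is
deliberate, since printed mean squares and printed components rarely
reconcile exactly after rounding.

Parameters and defaults:

* $k = 2.056$ — standardized selection differential for selecting the
  top 5%; configurable, reported in output metadata.
* GA uses $\sigma_p = \sqrt{PV}$ of the component table (this reproduces
  published GA rows; plot-level standard deviations do not).
* Classification scales use continuous boundaries — CV and GA%:
  low ≤ 10 < moderate ≤ 20 < high; H²: low ≤ 30 < medium ≤ 60 < high.
  The conventional printed scales leave gaps (10–11, 20–21, …); a value
  of 10.05 falls in such a gap and is classified *moderate* here.

## Qualitative diversity

$H' = -\sum_i p_i \ln p_i$ over descriptor classes (the source formula
omits the sign, but every published value is positive, so the negative
sum is implemented), with $0 \ln 0 = 0$. Equitability is $H'/\ln S$.
The default richness basis is the **number of accessions scored** — only
$\ln 345$ reproduces the published equitability values (1.41/ln 345 =
0.24) — while the textbook basis $S$ = number of declared classes is an
explicit option. Per-genotype consensus scores are the modal category
across plots and locations, ties broken by the first-declared category.
The chi-square column is an equiprobable-null heterogeneity test
($E_i = n/S$ over declared classes, df $= S-1$): the published df and
chi-square values for this table family are typographically garbled, so
the package documents its own reinterpretation and excludes those columns
from any acceptance claim.

## Multivariate stages

Correlations are pairwise-complete Pearson with two-sided t-tests. PCA is
an eigen-decomposition of the correlation matrix of z-standardized
(sample sd, $n-1$) trait means; sign convention: each loading vector's
largest-magnitude element is positive; components with eigenvalue > 1
are marked retained, and loadings with $|\lambda| \ge 0.30$ (inclusive,
configurable) are flagged important. Published proportion-of-variance
rows for this panel are not consistent with 13-trait standardized PCA,
so PCA claims are property-based only (trace = number of traits,
reconstruction of the correlation matrix, score orthogonality).

Clustering offers both methods the source material conflates: UPGMA
(average linkage on Euclidean distances of standardized traits; `hclust`
heights are the average inter-cluster distance, so the 1-D points
(0, 1, 5) merge at 1 and then 4.5) and seeded k-means (Hartigan–Wong
with 10 restarts rather than k-means++; determinism comes from the seed,
and cluster ids are relabelled by descending mean of a ranking trait —
grain yield in the default pipeline — so reported cluster numbers are
stable). Standardization before clustering is deliberate: Euclidean
distance on raw scales would be dominated by yield (variance ~10⁶ kg²/ha²
against ~18 ppm² for zinc).

## The synthetic panel: what it emulates and what it does not

`sorghum_sim_config()` states the simulated world once:

* 341 tests + 4 checks, 22 blocks, 2 locations; checks in every block,
  tests assigned one block each by round-robin after a seeded shuffle.
* 13 quantitative/count traits with the panel's published means and
  genotypic (GV) / environmental (EV) variance magnitudes. The published
  tables do not separate G×E from plot residual, so EV is split evenly:
  $\sigma^2_{g\times e} = \sigma^2_{res} = EV/2$; block variance is set
  to $EV/2$ and location variance to $EV$. These splits are stated
  choices, not fitted quantities, and are not revisited.
* Genotype effects are multivariate normal across traits with
  correlations Fe–Zn 0.32, yield–Fe −0.26, yield–Zn −0.17 (the published
  phenotypic associations, imposed at the genetic level).
* Count traits (shoot fly, stem borer) are Poisson with effects acting
  on the log scale, variances rescaled by $1/\text{mean}^2$ so the
  configured magnitudes act as squared coefficients of variation; the
  square-root transform downstream is exercised naturally.
* 10 qualitative descriptors drawn once per genotype from the published
  class-proportion vectors.

What a green test does **not** establish: the generator has no spatial
field trend, no genotype-specific missingness mechanism, no measurement
error structure specific to XRF nutrient assays, and independent block
effects rather than the serial correlation real fields show. Recovery of
H² within ±0.05 over 200 replicates (the acceptance criterion) therefore
validates the estimator chain — simulate → adjust → combined ANOVA →
components — not the field realism of the variance magnitudes. A known,
accepted bias: adjustment noise from the 4 checks inflates the estimated
EV by roughly $\sigma^2_{res}/4$, giving a mean H² underestimate of
about 0.02 at the yield-like configuration; the truncation at zero keeps
the null case ($\sigma^2_g = 0$) below 0.05 at panel scale (341 tests),
though not for much smaller collections.

## Numerical and interface choices

* Values are carried as text in the observation table so quantitative
  measurements and category labels share one long format; numeric
  conversion happens at the point of use, and the sqrt transform records
  provenance so it cannot be applied twice.
* The count transform is plain $\sqrt{x}$; $\sqrt{x + 0.5}$ is a flag.
* Missing values are empty CSV fields and are never imputed.
* Run configs are JSON (`jsonlite`), the one structured format already
  in the dependency set; the manifest records parameters, seeds,
  aggregated warnings and MD5 checksums, and reruns are byte-identical.
* Per-replicate seeds in the recovery harness are master seed +
  replicate index, so any replicate can be reproduced alone.
* Newick export of dendrograms goes through `ape`.

## Known limitations

* No REML/BLUP estimation, no row–column or spatial adjustment, no
  narrow-sense heritability — all out of scope by design.
* The combined ANOVA's G×E test against pooled intra-block error is a
  stated approximation (effective replication 1), not an exact F test.
* Single-location heterogeneity of error variance is not modelled when
  pooling.
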