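---
title: "Measuring household socioeconomic position with Mokken scale analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring household socioeconomic position with Mokken scale analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mokkensep)
```

## The measurement problem

Health surveys in low- and middle-income settings rarely carry reliable
income or expenditure data, so household socioeconomic position (SEP) is
usually proxied by a basket of asset-ownership questions — does the
household own a television, a refrigerator, a motorbike, and so on. The
standard construction is a principal components analysis (PCA) of the
asset indicators, with the first component taken as the wealth index and
households cut into quintiles. PCA, however, assumes continuous,
multivariate-normal data, which a set of 0/1 ownership indicators is not.

`mokkensep` implements a nonparametric item response theory alternative:
Mokken scale analysis. The idea starts from a Guttman scale — items
ordered from "easy" (a bucket) to "hard" (a car), where owning a hard item
implies owning all easier ones. Real data violate that determinism, so the
Mokken model makes it probabilistic: household $h$ owns item $i$ with
probability $P_i(\theta_h)$, where $\theta_h$ is the household's latent
SEP and each $P_i$ is a monotonically increasing item response function
(IRF). Nothing parametric is assumed about the $P_i$.

Two nested models organise the assumptions:

* **Monotone homogeneity (MMH)**: unidimensionality, local independence,
  and monotone IRFs. Under MMH the plain sum of owned items stochastically
  orders households on $\theta$ — the Mokken SEP score is an unweighted
  sum, with no loadings to estimate.
* **Double monotonicity (DMM)**: MMH plus *non-intersection* of the IRFs
  (invariant item ordering, IIO). Under DMM the item difficulty ordering
  is the same at every level of SEP, so items can be ranked "hardest to
  easiest" for the whole population at once.

## Loevinger's H coefficients

For an item pair, call the less popular item the *harder* one (ties go to
the lower column index). A *Guttman error* is a household owning the
harder item but not the easier. With $F_{ij}$ the observed error count and
$E_{ij} = n\,p_h(1-p_e)$ the count expected under independence,

$$H_{ij} = 1 - \frac{F_{ij}}{E_{ij}}
         = \frac{\mathrm{cov}(X_i, X_j)}{p_h(1 - p_e)},$$

and the item and scale coefficients are the ratio aggregates
$H_i = 1 - \sum_j F_{ij} / \sum_j E_{ij}$ and
$H = 1 - \sum_{i<j} F_{ij} / \sum_{i<j} E_{ij}$. The covariance identity
is used as the canonical computation (it is unaffected by the tie
designation) and the error-count form is kept as an independent oracle in
the test suite; both must agree to $10^{-12}$. $H = 1$ characterises a
perfect Guttman pattern, $H = 0$ independence. Conventional bands label
items and scales weak (.3–.4), medium (.4–.5) and strong (> .5), with .3
the customary floor below which an item is unscalable. Computed on the
*transposed* matrix (households as items, after dropping all-own/own-
nothing households), the same statistic $H^T$ summarises how accurately
the item ordering holds across households.

Standard errors for the $H_i$ come from a seeded nonparametric bootstrap
over households (default 1000 replicates). No closed-form delta-method
variant is hard-coded; the bootstrap keeps one mechanism for point
uncertainty and the pair-positivity test alike. Replicates in which an
item becomes constant are dropped and counted; more than 10% dropped
triggers a warning.

## Automated item selection (AISP)

`aisp()` partitions the pool bottom-up: seed a scale with the pair
maximising $H_{ij}$ among significantly positive pairs with
$H_{ij} \ge c$; repeatedly add the unassigned item that is significantly
positively related to every member, keeps its within-scale $H_i \ge c$,
and maximises the augmented scale's $H$ (ties: higher $H_i$, then lower
column index); close the scale when no item qualifies and restart on the
remainder. Defaults are $c = 0.3$ and a one-sided 5% bootstrap percentile
test of $H_{ij} > 0$. Because $H_{ij}$ depends on the pair only through
its 2×2 cross-table, the household bootstrap for that test reduces
exactly to multinomial resampling of the four cell counts, which keeps
the procedure fast and seed-deterministic. No multiple-testing correction
is applied across pairs; the number of tests performed is logged so users
can impose their own.

The tie-break rules and the positivity test are design choices: the
classic sequential procedure is specified only up to them, and they are
stated (and logged per decision) so a run is exactly reproducible.

## Restscore checks and iterative removal

The restscore $R_{(-i)}$ — a household's sum over the scale items
excluding the item(s) under examination — is the conditioning variable
for both model checks. Households are grouped by merging adjacent
restscore values left-to-right until every group reaches `minsize`
(default $\lfloor n/10 \rfloor$ for $n \ge 500$, else
$\max(50, \lfloor n/5\rfloor)$; an undersized remainder joins the last
group).

* **Monotonicity**: for each item, the ownership proportion is compared
  across every ordered pair of restscore groups. A later group falling
  below an earlier one by more than `minvi` (default 0.03) is a
  violation; it is *critical* when a one-sided two-proportion z-test is
  significant at `alpha` (default 0.05).
* **IIO**: for each item pair (harder = less popular overall), groups are
  formed on the restscore excluding both. A group where the harder item
  is more popular than the easier by more than `minvi` is a violation;
  it is critical when a one-sided sign test on the group's discordant
  households (those owning exactly one of the two items) is significant.
  The sign test was chosen because it respects the pairing of the two
  items on the same households.

`iterative_iio_removal()` removes the item with the most critical
violations (ties: larger maximum violation, then lower $H_i$, then lower
index), re-runs the check, and stops when no critical violations remain
or fewer than three items would survive. "Critical" is deliberately a
joint magnitude-plus-significance criterion, configurable through
`check_config()`, since different conventions exist.

## The PCA contrast

The comparison index mirrors common wealth-index practice but respects
the binary data: pairwise tetrachoric correlations (maximum likelihood
under a latent bivariate normal, thresholds fixed at the inverse-normal
margins, `mvtnorm` orthant probabilities, +0.5 continuity correction on
all cells only when a cell is empty) are assembled into a polychoric
correlation matrix, repaired by eigenvalue clipping if not positive
semi-definite, and eigendecomposed. Scores use Filmer–Pritchett
standardisation — each item centred by its popularity and scaled by its
Bernoulli SD — combined with first-component loadings sign-normalised so
that higher score means wealthier. At zero thresholds the ML estimate
must match the closed form $P(++) = \tfrac14 + \arcsin(\rho)/2\pi$ to
$10^{-4}$, which the tests enforce.

Quintiles, for either index, put the boundary of fifth $q$ at the
smallest score whose empirical CDF reaches $q/5$, and never split tied
scores — with an 11-point discrete sum score the fifths are therefore
only approximate, which is exactly how discrete wealth quintiles behave
in practice.

Reliability uses Cronbach's alpha on weighted items ($y_i = w_i x_i$;
unit weights for the Mokken sum, first-component loadings for the PCA
indices) with a Feldt F-distribution 95% interval; the CI method and the
natural-log transform of expenditure are both recorded in the output
metadata because other conventions exist.

## What the synthetic generator emulates — and what it does not

The generator is the package's stand-in for household survey microdata.
Responses follow a two-parameter logistic (2PL) IRF,
$P_i(\theta) = \mathrm{logit}^{-1}(a_i(\theta - b_i))$ with
$\theta \sim N(0,1)$: the simplest monotone family satisfying MMH, whose
equal-discrimination special case has non-intersecting IRFs — giving
clean negative controls for the IIO machinery. Violations are injected
deliberately: a unimodal ("middle households own it most") item for the
monotonicity check, and a high-discrimination crossing item for IIO.
Expenditure is log-normal with a trait loading calibrated so
$\mathrm{cor}(\log E, \theta) = 0.6$, the moderate association typical of
asset-expenditure comparisons.

The default fixture, `simulate_whs_like()`, has 17 items shaped like a
national asset module: 12 items on the dominant trait with popularities
spanning 0.3%–90% (difficulties found by inverting the quadrature
marginal at the target popularity), a correlated pair on a second
independent trait, and three trait-free noise items. At the default
$n = 3810$ the selection procedure recovers the planted 12/2/3 partition
for most seeds; for some seeds the rarest item (popularity 0.3%) fails
the pair-positivity test and lands unscalable — informative in itself
about rare items in pools of this size.

What the generator does **not** emulate: survey design (strata, clusters,
weights), missing data (the pipeline is complete-case by design, with
exclusion accounting), item-level guessing or response error beyond the
Bernoulli draw, and any dependence between the noise items and the trait.
Passing tests therefore demonstrate that the machinery is correct and
well-calibrated under the stated response model, not that any particular
real survey satisfies that model.

## Numerical and design choices

* Ties in popularity: the lower-index item is designated harder; the
  covariance form makes the coefficient independent of the designation.
* Constant items are rejected at matrix construction (they make
  $E_{ij} = 0$); constant household rows are dropped, with a message,
  only for $H^T$.
* $H^T$ is computed in $O(nk + n\log n)$ via suffix sums rather than
  materialising the $n \times n$ pair matrices.
* Tetrachoric optimisation is bounded at $|\rho| \le 1 - 10^{-6}$;
  hitting the bound flags the estimate as non-converged/clipped.
* All randomness (generator, bootstrap, significance tests) flows from
  explicit integer seeds; pair tests derive per-pair streams from the
  base seed, so partitions and logs are bit-reproducible.
* Problem sizes in the test suite (e.g. $n = 5000$, $k = 11$ for
  recovery and specificity runs; 20 seeds for the error-rate checks;
  $n = 3810$ for the default fixture) were chosen as the smallest sizes
  at which the asymptotic behaviour the checks rely on is clearly
  expressed.

## Worked example

```{r example, eval = FALSE}
report <- run_full_pipeline(pipeline_config(seed = 1))
report
#> SEP pipeline run (seed 1, config 709152d3)
#>   3810 households used ( 0.0 % excluded )
#> AISP partition: 2 scale(s), 3 unscalable item(s)
#>   scale 1 (H = 0.613): clock, electricity, television, motorbike, ...
#>   scale 2 (H = 0.940): bucket, agricultural_machine
#>   unscalable: bicycle, second_house, cars
#>   retained after IIO removal: clock, electricity, television, ...
#>   alphas: unit/full 0.683, pca/full 0.742, unit/scale 0.763, pca/reduced 0.761
#>   r(mokken, pca_full) = 0.988; r(mokken, log expenditure) = 0.546
```

The Mokken sum score and the full-pool PCA index rank households almost
identically (r ≈ 0.99) and correlate moderately with log expenditure
(r ≈ 0.55) — the pattern expected when a dominant monotone trait drives
both the assets and (noisily) the spending.

## Known limitations

Only dichotomous items are supported (the polychoric machinery covers
the 2×2 case); the AISP is the classic greedy procedure, not a global
search, so pathological pools can admit better partitions it will not
find; bootstrap standard errors approximate whatever variance estimator
another implementation may print only to bootstrap accuracy; and the
"critical violation" criterion is convention-dependent — replications of
published violation counts can hinge on `minvi` and `minsize` values
that papers rarely print.
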