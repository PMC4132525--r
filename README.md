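# mokkensep

Nonparametric item response theory scaling of household socioeconomic
position (SEP) from dichotomous asset-ownership data.

Epidemiologists and health-survey analysts usually proxy household wealth
with a principal components index over asset indicators, even though PCA
assumes continuous multivariate-normal data. `mokkensep` implements the
nonparametric alternative — **Mokken scale analysis** — end to end, and
carries the conventional polychoric-PCA index alongside it as a point of
contrast, so the two constructions can be compared on the same households
against an external criterion such as log expenditure.

## What it computes

* **Loevinger scalability coefficients.** For an item pair with harder
  (less popular) item *h* and easier item *e*,
  `H_ij = 1 − F_ij / E_ij = cov(X_i, X_j) / (p_h (1 − p_e))`, where `F`
  counts observed Guttman errors (harder owned, easier not) and
  `E = n p_h (1 − p_e)` is the count expected under independence. Item
  (`H_i`) and scale (`H`) coefficients aggregate the error ratios;
  `H = 1` is a perfect Guttman scale, `H = 0` independence, `H > .5` a
  strong scale. `H^T`, the same statistic on the transposed matrix,
  summarises the accuracy of the item (asset) ordering. Standard errors
  by seeded household bootstrap.
* **Automated item selection (AISP)**: greedy bottom-up partition of the
  pool into Mokken scales under the constraints `H_ij` significantly
  positive and within-scale `H_i ≥ c` (default `c = 0.3`), with a full
  decision log.
* **Restscore model checks**: monotonicity of the item response
  functions, and invariant item ordering (non-intersection) per item
  pair, with a configurable magnitude-plus-significance definition of a
  *critical* violation and iterative removal of the worst offender.
* **Wealth indices**: the Mokken SEP score (unweighted sum over the
  retained scale) and Filmer–Pritchett-standardised scores on the first
  principal component of the tetrachoric/polychoric correlation matrix;
  CDF-based quintiles that never split tied scores.
* **Evaluation**: weighted Cronbach's alpha (Feldt 95% CI) and
  Pearson/Spearman comparisons of all indices with log expenditure,
  plus per-quintile expenditure summaries.
* **Synthetic households**: a seeded 2PL latent-trait generator with
  log-normal expenditure, multi-trait blocks, noise items, and injectors
  for non-monotone and crossing items, so every stage is testable
  without survey microdata.

## Worked example

```r
library(mokkensep)
report <- run_full_pipeline(pipeline_config(seed = 1))
report
#> SEP pipeline run (seed 1, config 709152d3)
#>   3810 households used ( 0.0 % excluded )
#> AISP partition: 2 scale(s), 3 unscalable item(s)
#>   scale 1 (H = 0.613): clock, electricity, television, motorbike,
#>     video_dvd, telephone, refrigerator, magazine, washing_machine,
#>     computer, mobile_phone, dishwasher
#>   scale 2 (H = 0.940): bucket, agricultural_machine
#>   unscalable: bicycle, second_house, cars
#>   retained after IIO removal: clock, electricity, television, motorbike,
#>     video_dvd, telephone, refrigerator, magazine, washing_machine,
#>     computer, mobile_phone, dishwasher
#>   alphas: unit/full 0.683, pca/full 0.742, unit/scale 0.763, pca/reduced 0.761
#>   r(mokken, pca_full) = 0.988; r(mokken, log expenditure) = 0.546
```

Reading the output: of the 17 simulated asset items, the selection
procedure recovers the twelve planted on the dominant wealth trait as
scale 1 (a strong scale, `H = 0.61`), pairs off the two second-trait
items as scale 2, and leaves the three noise items unscalable. The
restscore checks find no invariant-item-ordering violations (equal
discriminations were simulated, so none should exist), the 12-item sum
score is highly reliable (alpha = 0.76), and it agrees with the
polychoric-PCA index almost perfectly (r = 0.99) while both correlate
moderately (r ≈ 0.55) with log household expenditure.

To run the same pipeline on real data, point the config at a CSV of
households × items (plus an expenditure column) and declare any count
columns to dichotomise:

```r
cfg <- pipeline_config(input = "households.csv",
                       dichotomise = list(cars = 1),  # count >= 1 -> owned
                       out_dir = "sep_output", seed = 1)
report <- run_full_pipeline(cfg)
```

A thin CLI with `simulate`, `msa`, `pca`, `compare` and `run` subcommands
is installed at `inst/scripts/sep_pipeline.R`.

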