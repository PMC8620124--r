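# ethnosurvey

Quantitative ethnobotany of the miracle plant (*Synsepalum dulcificum*):
use-value and informant-agreement indices, the KMTO classification of
traditional-knowledge acquisition paths, a contingency/count-model
statistical harness, and CART-style driver analysis of the willingness
and readiness to cultivate — plus a seeded synthetic survey generator
that emulates the structure of a 510-respondent, nine-group survey in
Benin and Ghana so the whole pipeline is testable without field data.

It is written for ethnobotanists and survey biostatisticians who work
with the standard two-table layout of such studies: a respondents table
(demographics, tree ownership, perceptions, cultivation intent) and a
use-reports table (one row per respondent × cited use, with plant part,
preparation and knowledge source).

## The indices and models at the core

* **Use value** (Phillips & Gentry): per respondent
  `UVj = Σ URi` (distinct use-report citations), species level
  `UV = Σ UVj / N`. Disaggregations by use category and plant part keep
  the full-N denominator, so category use values sum to the overall
  index.
* **Informant agreement ratio**: for a scope with `nr` citations over
  `na` distinct plant parts, `IAR = (nr − na)/(nr − 1)`; 1 at full
  consensus, 0 with no agreement, undefined at a single citation.
* **KMTO**: each knowledge-acquisition event is coded as
  (Kernel internal/external, Mutation transition/transversion, Type
  vertical/horizontal/transversal, Order 1/2/0). The attribute product
  has 36 paths; the structurally attainable subset has 16.
* **Statistical harness**: chi-square equal-proportion tests;
  independence tests with Fisher-exact fallback when any expected cell
  is below 5 (Monte-Carlo for tables beyond 2×2); Poisson GLMs switching
  to quasi-Poisson when the Pearson dispersion exceeds 1.5; Fisher
  r-to-z comparison of correlations.
* **Drivers**: in-package CART (Gini / anova splits, category-ordering
  split search, weakest-link cost-complexity pruning with seeded
  cross-validation) for willingness to cultivate, maximum acreage and
  maximum seedling price.

## Worked example

```r
library(ethnosurvey)

ds <- generate_dataset(generator_config(seed = 7))
ds
#> survey_dataset: 510 respondents, 1287 use reports
#>   groups: Adja, Aizo, Akan, Ewe, Fon, Ga-adangbe, Holli, Sahoue, Weme
#>   provenance: synthetic; seed=7; cfg_checksum=562395

total_use_value(ds)
#>     scope n_respondents       uv        sem
#> 1 overall           510 2.523529 0.05256316
```

On average each synthetic respondent cites about 2.5 distinct uses —
the generator draws each documented use with its published citation
propensity, so this sits near the study-scale use value (≈ 2.45).

```r
head(iar_table(ds, "category"), 3)
#>              scope  nr na       iar
#> 1             food 498  1 1.0000000
#> 2 magico_spiritual 181  6 0.9722222
#> 3        medicinal 360  7 0.9832869
```

Food has perfect agreement (every citation is the fruit-as-sweetener
use); the other categories spread over several plant parts.

```r
pf <- path_frequencies(ds)
head(pf[order(-pf$count), ], 3)
#>      kernel     mutation     type order count proportion
#> 6  internal   transition vertical     1   509 0.39549340
#> 10 internal transversion vertical     1   207 0.16083916
#> 7  internal   transition vertical     2   113 0.08780109
```

The modal acquisition path is internal–transition–vertical–order 1:
knowledge passed from father to son, the dominant transmission route.

```r
r <- ds$respondents
w <- r$willing_to_cultivate
fit_regression_tree(r[w, c("schooling", "perceived_growth")],
                    r$max_acreage_ha[w])
#> regression tree, 4 leaves
#> node: mean=0.3843 n%=100.0 [schooling in {literate,none,primary,secondary}]
#>   node: mean=0.3176 n%=95.8 [schooling in {none}]
#>     leaf: mean=0.2132 n%=46.4
#>     node: mean=0.4158 n%=49.4 [perceived_growth in {moderate,slow}]
#>       leaf: mean=0.3742 n%=45.6
#>       leaf: mean=0.9155 n%=3.8
#>   leaf: mean=1.897 n%=4.2
```

The acreage tree isolates university-schooled respondents (≈ 1.9 ha
offered), then no-schooling respondents (≈ 0.21 ha), then splits the
intermediate-schooling group by perceived growth rate — the driver
structure the generator encodes (1.8 / 0.2 / 0.4 / 0.83 ha strata).

`run_pipeline(run_config(out_dir, generator = generator_config(seed = 7)))`
chains simulate → validate → indices → kmto → associations → drivers and
writes one JSON artifact per stage plus a checksummed manifest.

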