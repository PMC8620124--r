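---
title: "Methods: use-value indices, KMTO knowledge paths and cultivation drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: use-value indices, KMTO knowledge paths and cultivation drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnosurvey)
```

## The scientific setting

`ethnosurvey` analyses quantitative-ethnobotany interview data on the
miracle plant (*Synsepalum dulcificum*), a West African tree whose fruit
pulp contains the taste-modifying glycoprotein miraculin. The survey
design it targets interviews respondents from nine sociolinguistic
groups in Benin (Adja, Aizo, Fon, Holli, Sahouè, Wémé) and Ghana (Akan,
Ewe, Ga-adangbe) and records, per respondent, demographics, tree
ownership, perceptions of the species' biology and availability, and
cultivation intent; and, per cited use, the use category, the ICPC2-derived
body system for medicinal uses, the plant part, the preparation, and who
taught the respondent that use.

Two tables carry the data: one row per respondent and one row per
respondent-by-use citation. Everything downstream — indices, knowledge-path
classification, association tests, tree models — consumes this pair.

## Use-value and agreement indices

The use value of respondent $j$ is the count of their distinct use
reports, $UV_j = \sum_i UR_i$, and the species-level index is the mean
$UV = \sum_j UV_j / N$ over all $N$ respondents (Phillips & Gentry). Two
decisions were genuinely open:

* **The counting unit.** A "use report" is taken as a distinct
  (use label, plant part) pair per respondent; exact duplicate rows
  collapse. This makes $UV_j$ invariant to row order and to accidental
  double entry, at the cost of never counting a repeated identical
  citation twice — the natural reading of a citation index.
* **Disaggregated denominators.** Category- and part-level use values
  restrict the numerator to qualifying citations but keep the full-$N$
  denominator, so category use values add up exactly to the overall
  index (partition additivity). Per-respondent-stratum use values instead
  partition the respondents and report per-level means.

The informant agreement ratio for a scope (use category or body system)
with $nr$ citations over $na$ distinct plant parts is
$IAR = (nr - na)/(nr - 1)$: 1 at full consensus on one part, 0 when every
citation names a different part, undefined (reported `NA`) when $nr = 1$.
Display rounding is half-up to two decimals; a handful of published
agreement tables instead truncate (e.g. $90/94 = 0.9574$ shown as 0.95),
so exact-value comparisons in the tests use only cells where both
conventions agree.

Correlations between $UV_j$ and tree counts use `stats::cor.test`;
Spearman p-values are exact for $n \le 10$ and asymptotic otherwise.
Correlation differences are compared with Fisher's r-to-z transform,
$Z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$.

## The KMTO knowledge-acquisition framework

Each citation's knowledge source is coded on four attributes: **K**ernel
(internal to the family line vs external), **M**utation (transition =
same-sex transfer, transversion = cross-sex), **T**ype (vertical =
another generation, horizontal = same generation, transversal =
self-learning) and **O**rder (1 = parent, 2 = grandparent, 0 =
otherwise). The full attribute product has $2 \times 2 \times 3 \times 3
= 36$ paths; under the framework's own structural rule — vertical paths
carry order 1 or 2, horizontal and transversal paths carry order 0 —
only 16 are attainable. `enumerate_paths()` exposes both spaces without
preferring either, because the framework is normally quoted by its
36-path product even though most of those cells are structurally empty.

Conventions for source relations the framework leaves open (each
isolated in one lookup table, `kmto_relation_table()`):

* spouses: internal, horizontal (same generation, inside the household);
* uncles/aunts: internal, **vertical with order 0** — orders 1 and 2 are
  reserved for progenitors and grandparents, yet an uncle is another
  generation. This is the single classifier output that is not
  structurally valid, and the package treats that as a property of the
  framework, not a bug: the tests assert it explicitly;
* cousins: internal, horizontal, order 0;
* self-learning: internal, transition by convention (source = self,
  hence same sex), transversal, order 0, with `source_gender`
  `not_applicable` enforced;
* friends, community members, healers: external, horizontal, with the
  source gender as reported by the informant (never inferred).

Attribute-state balance is tested by chi-square goodness of fit over the
full state set of each attribute (so a single observed state yields the
maximal statistic rather than a degenerate table), and attribute-by-use-
category independence through the shared harness below.

## Statistical harness

* `equal_proportions_test()` — chi-square goodness of fit against equal
  expected proportions, df $= k - 1$.
* `independence_test()` — Pearson chi-square without continuity
  correction when every expected cell is at least 5; otherwise Fisher's
  exact test, exact for 2×2 and Monte-Carlo (100 000 seeded table draws)
  for larger tables. The any-cell-below-5 trigger is the conventional
  rule for these survey tables; the Monte-Carlo size is a pragmatic
  choice giving p-value noise well under 0.005.
* `fit_count_model()` — log-link Poisson regression via `stats::glm`
  (IRLS to relative tolerance 1e-8, at most 100 iterations). The Pearson
  dispersion $\sum r_i^2/(n-p)$ is computed from the Poisson fit; above
  the threshold 1.5 the standard errors are scaled by its square root
  and the family recorded as quasi-Poisson. Point estimates never change
  between the two families — only inference does — and the tests pin that
  down. The 1.5 threshold is exposed as an argument; equidispersed data
  sit near 1 and the survey's tree counts sit far above it, so the exact
  cut is not delicate.

## The synthetic survey generator

No interview data accompany the analysis, so the generator is the test
bed: it emulates the study conditions and every downstream module is
exercised on its output. Its defaults *are* those conditions:

* group sizes 53/53/51/54/56/87/55/50/51 (N = 510) and per-group
  demographic marginals for gender, age category, schooling, activity,
  religion and migratory status, taken from the survey's demographic
  table; ages are uniform integers inside the drawn category's bounds
  (young 18–29, adult 30–59, old 60–90 — the bounds are published, the
  interior is not);
* tree ownership with probability 366/510; owners' counts follow a
  zero-truncated negative binomial (dispersion size 1.0 — the survey
  itself needed a quasi-Poisson, so equidispersed counts would be the
  wrong emulation) whose *truncated* mean is calibrated by root-finding
  to the configured group mean, keeping "owners have at least one tree"
  from biasing the published Akan (14.15) and Holli (1.68) means;
* one catalogue row per documented use with its citation count out of
  510 and its admissible part list; each eligible respondent cites a row
  independently with probability citations/eligible-N (sweetener
  497/510), parts drawn uniformly from the row's list. Magico-spiritual
  rows are restricted to Benin and firewood to the Ewe, as observed.
  Summing the catalogue's citation counts gives an expected overall use
  value of 1255/510 ≈ 2.46, consistent with the published 2.45 ± 0.06 —
  a consequence of using the published counts, not a tuned quantity;
* knowledge sources drawn from a father-dominant relation distribution
  (father 0.40, mother 0.12, grandparents 0.16, …) so the modal path is
  the first-order paternal transition observed in the field; gender-
  unconstrained sources are men with probability 0.75;
* willingness to cultivate from a tree-structured rule — Akan/Ga-adangbe
  low; otherwise taboo knowledge, then market perception interacting
  with schooling — whose probabilities are shifted on the logit scale
  (root-finding on the realized respondents) so the expected marginal
  equals the published 45%. The rule gives the classification tree
  recoverable structure instead of an unconditional coin flip;
* for willing respondents, maximum acreage from a gamma (shape 4,
  strictly positive and right-skewed like the stated USD/ha ranges) with
  stratum means 0.2 ha (no schooling), 1.8 ha (university) and 0.4/0.83
  ha (intermediate schooling, by perceived growth), and seedling price
  from ordered activity/ownership/age/group rules (handcraft makers
  high, the elderly ≈ 0.41 — the source prints an ambiguous "0.4l" —,
  2.1 for the young/adult Adja–Aizo–Akan–Wémé acceptable-fruiting
  intermediate-schooling stratum, 0.46 otherwise). Setting the gamma
  shape to 0 collapses every draw to its stratum mean, which the
  degenerate-noise tests rely on.

Quantities the survey reports only graphically — per-group tree-count
means other than Akan and Holli, taboo/superstition/market rates,
per-group use propensities — are one-time order-of-magnitude
calibrations (Ghana groups own more trees than Benin groups; taboos are
concentrated in Benin) and are flagged as such here rather than sourced
values.

What the generator deliberately does **not** emulate: free-text content
(local names, recipes), spatial structure, missing data, respondent-level
correlation between citing one use and citing another beyond the shared
demographics, and interviewer effects. Tests passing on this generator
therefore show the *machinery* recovers known structure under realistic
noise — not that the field data satisfy the generative assumptions.

## Classification and regression trees

The cultivation-driver analysis uses in-package CART: greedy binary
splits maximizing the Gini impurity decrease (binary classification) or
the between-node sum-of-squares reduction ("anova" regression).
Categorical features are split by ordering their levels on the
positive-class rate or mean response and scanning the ordered cut
points — exact for these two criteria by the standard ordering theorem —
with an exhaustive-bipartition oracle retained in the tests for up to 8
levels. Numerical choices:

* defaults `min_split = 20`, `min_bucket = ceiling(min_split/3)`,
  `complexity = 0.01`, 10-fold cross-validation — the conventional
  defaults of the rpart tool family, which the published analysis ran
  without reported tuning;
* a split is kept only if its impurity decrease is at least
  `complexity` times the root impurity;
* ties in split quality (within 1e-10) break by feature name, then by
  the lexicographic left-level set, for cross-platform determinism;
* pruning is weakest-link cost-complexity: `prune_tree(..., alpha =)`
  prunes at a fixed penalty (0 leaves the tree unchanged, `Inf` collapses
  it to the root), and with no `alpha` the candidate penalties are the
  tree's own weakest-link sequence evaluated at geometric midpoints,
  with the subtree minimizing the seeded cross-validated risk selected
  (ties toward the smaller tree);
* prediction routes unseen categories in the majority direction recorded
  at training;
* only willing respondents enter the acreage and price regressions, as
  readiness is defined conditional on a favourable cultivation decision.

On generator output the acreage tree recovers the university-stratum and
no-schooling leaf means well within 15% of their configured 1.8 and 0.2
ha, and the willingness tree's first split falls in the
group/taboo/market driver set in nearly every seed — the structural
signature of the published driver analysis. Full published tree
topologies are not reproducible without the raw survey and are not
claimed.

## Problem sizes and runtime

The default test and acceptance runs use the study-scale N = 510 dataset
where a single replicate suffices, a ninth-scale dataset for property
loops over many seeds, and 10 pooled replicates (≈ 2 300 willing
respondents) for the regression-tree recovery — sizes at which every
stochastic check has comfortable margin while the whole suite stays
under a minute on one core.

## Known limitations

* The agreement-ratio cap of seven distinct parts reflects this species'
  part vocabulary; other taxa would need a wider enum.
* The Monte-Carlo Fisher fallback returns no test statistic, only a
  p-value, matching `stats::fisher.test`.
* Quasi-Poisson here means scaled standard errors, not a full
  quasi-likelihood estimating-equation treatment of non-log-linear
  variance.
* The classification trees handle binary outcomes only (willing / not
  willing); multi-class outcomes are out of scope.
* Survey weighting, imputation and geocoding are deliberately absent.
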