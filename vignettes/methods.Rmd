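---
title: "Measuring individual specialisation in factorial mesocosm experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring individual specialisation in factorial mesocosm experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichevar)
```

`nichevar` analyses repeated individual resource-use measurements from
replicated experimental populations. This vignette documents the models and
procedures, the defaults and why they were chosen, what the synthetic-data
generator does and does not emulate, and the numerical decisions a
maintainer should know about.

## The Shannon niche partition

The raw object is a count matrix for one population: rows are individuals,
columns resource categories (prey taxa or microhabitats), cells the number
of items or sightings summed over all sampling occasions. Writing `p_ij`
for the proportion of individual $i$'s use in category $j$, `p_i.` for
individual $i$'s share of the population's total count, `q_j` for the
pooled population proportions, and `gamma_ij` for individual $i$'s share of
the population's use of category $j$, the total niche width (TNW, the
Shannon entropy of `q` in nats) decomposes additively as

$$\mathrm{TNW} = \mathrm{WIC} + \mathrm{BIC},$$

where WIC is the count-weighted mean entropy of individual rows
($\sum_i p_{i\cdot} H(p_{i\cdot j})$, the within-individual component) and
BIC is the between-individual component. In information terms, with
individual identity $I$ and resource category $J$ distributed according to
the counts, $\mathrm{TNW} = H(J)$, $\mathrm{WIC} = H(J \mid I)$, and
$\mathrm{BIC} = I(I;J) = H(I) - \sum_j q_j H(\gamma_{\cdot j})$. BIC is
implemented through the `gamma` form rather than as the difference
`TNW - WIC`, and the additivity is enforced as a test invariant
(`1e-10` on thousands of random matrices) rather than by construction —
printed versions of these equations circulate with typographical sign
errors, and the mutual-information identity is the unambiguous form.

The specialisation index is `1 - WIC/TNW`: 0 when all individuals have
identical proportion rows, 1 when every individual is confined to a single
category (zero individual entropy). It is undefined when the population
uses a single category (TNW = 0); `niche_decompose()` raises a classed
error rather than returning 0 or 1, because a one-category population
carries no information about specialisation.

Two conventions matter and are deliberate:

* **Natural logarithms.** All entropies are in nats.
* **Count weighting.** `p_i.` is count-proportional, so heavily sampled
  individuals weigh more in WIC, and `q` is computed from summed counts
  (equivalently $q_j = \sum_i p_{i\cdot}\,p_{ij}$). The alternative
  (equal-weight individuals) is *not* offered for the decomposition; equal
  weighting is used only for tank mean compositions (below), where it
  prevents one well-sampled fish from dominating a tank's composition.

## Filtering rules

Raw records pass through three explicit gates, in order:

1. `build_matrix()` sums counts over sampling occasions per individual.
2. `drop_empty_individuals()` removes individuals whose samples were all
   empty (they carry no niche information), together with categories that
   become unused.
3. `filter_tanks()` retains a population only if at least 3 individuals
   each have at least 3 niche measures (items or observations — the row
   sum). "Three measures" is read as *three items in total*, not three
   occasions or three distinct categories: the same rule must serve diet
   items and habitat sightings, and the row sum is the only reading that
   treats both identically. Individuals below the per-fish threshold are
   not removed from retained tanks — the rule gates tanks, not fish.

Replacement individuals (same tank, new identifier) are treated as distinct
individuals throughout; no identity merging is attempted.

## The Monte Carlo null

`monte_carlo_test()` asks whether the observed index exceeds what
stochastically sampling generalists would produce: each replicate redraws
every individual's row as a multinomial sample of its observed size from
the pooled proportions `q`, preserving per-individual sampling effort
exactly. The p-value uses the add-one convention
$(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(n_{\mathrm{reps}} + 1)$, so it
is never 0 and the test is valid at finite replicate counts. The default is
999 replicates; the replicate count is a precision knob, not a model
parameter.

Replicates in which all redrawn counts land in one category have an
undefined index and are redrawn (capped, with a warning) — they are a
measure-zero nuisance of small samples, not evidence about specialisation.

This is a plug-in null (`q` is estimated from the same data), so exact
uniformity of p-values is not guaranteed. Calibration at the package's
default sampling effort (4 fish, ~4.3 items each) is verified by
simulation in the acceptance suite: 500 generalist populations give a
rejection rate near the nominal 5% (band 3–7%). At much larger per-fish
samples the plug-in approximation drifts mildly anti-conservative
(~10% at 50+ items per fish in exploratory runs); users with deeply
sampled individuals should interpret borderline p-values accordingly.

## Composition analyses

Tank mean compositions (each individual row-normalised, then averaged with
equal weight per individual) feed Bray–Curtis dissimilarities and the
standard multivariate battery, all through vegan — the same implementations
practitioners use directly:

* `permanova_two_way()` wraps `vegan::adonis2` with sequential ("by terms")
  entry in the order competition, predation, interaction. Sequential entry
  is the cited default; with an unbalanced design the per-term $R^2$
  depends mildly on this choice, so the assessment mode is exposed
  (`by = "margin"` available) rather than hidden. Permutations are free
  (unrestricted), matching an unblocked design; an explicit permutation
  matrix can be supplied for exhaustive enumeration on small designs.
* `dispersion_homogeneity()` wraps `vegan::betadisper` (group centroids,
  not spatial medians) with a permutation F-test.
* `simper_contributions()` wraps `vegan::simper` (999 permutations by
  default). The pipeline's contrast pools competitor presence across
  predation levels, the two-group contrast consistent with reporting
  category proportions "with vs without" the competitor. Groups with a
  single member leave nothing to permute; the decomposition is then
  computed directly and p is NA.
* `nmds_ordination()` wraps `vegan::metaMDS` on the precomputed
  dissimilarity (no autotransformation), k = 2, 20 random starts, reporting
  Kruskal stress-1. A standalone `kruskal_stress()` evaluates the stress of
  any fixed configuration via an own pool-adjacent-violators fit (ties
  ordered by configuration distance), so the stress criterion itself is
  testable against `stats::isoreg` independently of the optimiser.

## Factorial inference

Per-tank responses (`1 - WIC/TNW`, TNW, WIC, BIC) are analysed with OLS
under sum-to-zero contrasts — the coding under which Type III sums of
squares test the usual factorial hypotheses. The decision flow mirrors
standard practice for unbalanced 2x2 designs: the interaction is judged
from Type III SS; if non-significant at $\alpha = 0.05$, main effects are
reported from Type II SS (which respect marginality and are more powerful
absent an interaction), otherwise everything stays Type III. Both tables
come from `car::Anova`; when a fit is perfect (zero residual SS, as in
degenerate test fixtures) the same partition is computed by direct
projection of the sum-coded model matrix, since `car` refuses a zero
residual.

Partial eta squared is $SS_{\mathrm{term}}/(SS_{\mathrm{term}} +
SS_{\mathrm{resid}})$ using whichever SS type the decision flow selected
for that term. The diet BIC response is log-transformed (natural log, no
offset) by default in the pipeline — niche components are strictly
positive, and this response is right-skewed in practice. A habitat TNW
left-skew cannot be fixed by standard transformations, so the package
reports numeric residual diagnostics (skewness, excess kurtosis,
max/min cell-variance ratio with advisory flags at |skew| > 1 and ratio
> 4) instead of transforming silently.

`tukey_pairwise()` treats the design as a 4-level cell-means model:
Tukey–Kramer standard errors for unbalanced cells, adjusted p from the
studentized range distribution with 4 means and the residual df, and a
compact letter display built by insert-and-absorb. Post-hocs run whenever
any term in the ANOVA table is significant.

## What the generator emulates — and what it does not

`generator_config()` encodes a 36-tank, 2x2 competition x predation-risk
experiment: 9 tanks per cell, 4 fish per tank, 14 prey taxa whose baseline
composition is the focal species' average stomach-content profile
(cladoceran/chironomid-dominated; one taxon, a prey of the competitor only,
has baseline zero), and 8 microhabitat categories dominated by sand (43%)
and the water column (21%), with the remaining categories at 3–10%.

Individual heterogeneity is Dirichlet-multinomial: fish preferences are
Dirichlet with mean `q` and concentration `kappa`, so category $j$'s
preference variance is $q_j(1-q_j)/(\kappa+1)$ — the minimal model with
exactly the two variance layers WIC and BIC measure (within-individual
multinomial noise, between-individual preference spread).
`kappa = Inf` is the generalist sentinel used for null calibration.

Chosen defaults, fixed once:

* `kappa_diet = 2`, `kappa_habitat = 8` — moderate dietary IS, weaker
  habitat IS, the ordering seen in the study system.
* Competition: a benthic diet shift (daphniids down by 0.42 of the simplex,
  chydorids/chironomids/ostracods up) plus a 4-fold diet-kappa increase
  (homogenised individuals), and a wall-ward habitat shift.
* Predation: a 3-fold habitat-kappa increase; the interaction multiplies
  habitat kappa by 1/3, so in the combined cell the predator effect is
  cancelled by competitor presence — the antagonistic pattern the design
  is meant to detect.
* Sampling effort: 1–5 lavage sessions per fish, Poisson(1.7) items per
  non-empty sample, 15% empty samples — a realised mean of ~4.3 items per
  fish; Poisson(15.4) scheduled habitat sightings, ~13.5 realised after
  mortality.
* Mortality: each fish dies with probability 0.25 at a uniform time and
  its later sampling occasions are lost (binomial thinning). This drives
  tank attrition through the replication filter at a realistic rate for
  diet (~20 of 36 tanks retained at default effort).

Deliberate non-realisms, relevant when interpreting green tests: habitat
observation failure (unrecorded fish) is not modelled, so habitat attrition
is weaker than in real scan data; per-fish item counts are far less
overdispersed than real stomach contents (no 300-item outliers), which
makes the Monte Carlo null better calibrated but understates the power a
few deeply sampled fish contribute; empty samples are recorded as
zero-count placeholder rows so the empty-individual path is exercised; and
there is no behaviour, space, or prey dynamics — treatments act directly on
the generating parameters. Passing tests therefore demonstrate statistical
correctness and parameter recovery under the assumed data model, not
ecological realism of any particular effect size.

## Numerical and testing choices

* `0 log 0 = 0` throughout; entropy inputs validated to sum to 1 within
  `1e-9`.
* Additivity is asserted to `1e-10`; brute-force oracle agreement to
  `1e-12` over all 3x3 count matrices with entries in {0, 1, 2} (~17,000
  non-degenerate cases).
* Null-model calibration uses 500 simulated generalist populations at 999
  replicates; parameter recovery uses 200 populations per kappa in
  {0.5, 5, 50}; factorial type-I calibration uses 1,000 null simulations
  on the study's unbalanced 5/7/3/6 layout. These sizes give binomial
  standard errors comfortably inside the asserted bands while keeping the
  default test run fast.
* Permutation p-values use the add-one convention everywhere; the
  PERMANOVA permutation test is checked exactly against a 720-relabelling
  enumeration oracle on a 6-sample toy.
* All randomised stages accept a seed and record it in their results; the
  pipeline derives independent sub-seeds (fixed offsets) from one master
  seed, and a manifest reproduces a run exactly.

## Known limitations

* The index inherits the small-sample upward bias of plug-in entropy
  estimates: with ~4 items per fish, even generalist populations show
  observed indices around 0.25. Always read the index jointly with its
  Monte Carlo p-value.
* The Monte Carlo null conditions on observed row sums and pooled
  proportions; it tests stochastic resource sampling, not alternative
  nulls (e.g. resampling from the pooled item list), which are out of
  scope.
* No variance-based (continuous-trait) decomposition, no pairwise overlap
  indices, no mixed models or covariates; `replicate_paper()` requires the
  user to supply the original deposited data and a column mapping — the
  package never downloads data.
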