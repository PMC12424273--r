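# nichevar

Quantifying individual specialisation in replicated experimental
populations.

Many populations that look like generalists are collections of relative
specialists: each individual exploits only a subset of the resources its
population uses. `nichevar` implements the complete statistical workflow for
measuring this individual specialisation (IS) in replicated experiments —
the kind of design where small populations of a focal species (e.g. fish in
mesocosm tanks) are crossed against ecological treatments such as
interspecific competition and predation risk, and each individual is
sampled repeatedly for diet (serial gastric lavage) or habitat use (focal
scan observations).

## The statistics

For one population, individual-by-resource counts `n_ij` define the
proportions `p_ij` (individual *i*'s use of category *j*), `p_i.`
(individual *i*'s share of the population total), `q_j` (pooled population
use) and `gamma_ij` (individual *i*'s share of the population's use of
category *j*). The population's total niche width is partitioned with
Shannon entropies (natural log) into additive within- and
between-individual components:

    TNW = H(q)                         total niche width
    WIC = sum_i p_i. * H(p_i, .)       within-individual component
    BIC = H(p_.) - sum_j q_j H(gamma_, j) = TNW - WIC

`BIC` is the mutual information between individual identity and resource
category, so the additivity `WIC + BIC = TNW` is an exact information
identity. The specialisation index is the complement

    1 - WIC/TNW   (0 = identical generalists, 1 = every individual
                   confined to a single resource category)

Per-population significance comes from a Monte Carlo stochastic-generalist
null: each individual's counts are redrawn as a multinomial sample of its
observed size from the pooled proportions `q`, and the one-sided p-value is
`(1 + #[null >= observed]) / (n_reps + 1)`.

Around the index, the package reproduces the standard companion analyses:

* **composition shifts** — Bray–Curtis dissimilarity among tank mean
  compositions, two-way PERMANOVA (competition x predation, sequential
  terms), homogeneity of multivariate dispersion, SIMPER per-taxon
  contributions, and NMDS ordination (all via vegan);
* **factorial inference** — 2x2 ANOVA on per-tank `1 - WIC/TNW`, `TNW`,
  `WIC`, `BIC` with the interaction judged from Type III sums of squares
  and main effects from Type II when the interaction is non-significant
  (car), partial eta squared effect sizes, and Tukey HSD post-hoc
  comparisons with a compact letter display;
* **a synthetic-data generator** — Dirichlet-multinomial populations whose
  concentration parameter kappa controls between-individual heterogeneity
  (small kappa = strong specialisation, `Inf` = identical generalists),
  with treatment effects on composition and kappa, realistic sampling
  effort, empty stomachs and mortality-driven tank attrition, plus a
  ground-truth ledger for parameter-recovery tests.

## Worked example

```r
library(nichevar)

## a full synthetic 36-tank experiment (9 tanks in each cell of the
## competition x predation design, 4 fish per tank)
ex <- generate_experiment(generator_config(), seed = 42)

## one tank: decompose the niche and test the index against the null
m <- drop_empty_individuals(build_matrix(ex$diet_records, "T28", "diet"))$matrix
niche_decompose(m)
#> niche components (diet, tank 'T28'): 3 individuals, 5 categories
#>   TNW = 1.3624  WIC = 0.9637  BIC = 0.3988  (nats)
#>   1 - WIC/TNW = 0.2927
monte_carlo_test(m, n_reps = 999, seed = 1)
#> Monte Carlo specialisation test (tank 'T28')
#>   observed 1 - WIC/TNW = 0.2927
#>   null mean = 0.2101 (999 replicates)
#>   one-sided p = 0.168
```

The tank's three fish use five prey categories with a pooled niche width of
1.36 nats, of which 29% lies between individuals; with only ~4 items per
fish that is not distinguishable from stochastic generalists sampling the
shared pool (p = 0.17).

```r
## the full pipeline: filtering, per-tank components + null tests,
## composition tests, factorial ANOVA with post-hocs
res <- run_full_analysis(ex$diet_records, ex$habitat_records, ex$design,
                         n_reps = 999, n_perm = 999, seed = 42)
res
#> == diet: 14 tanks retained (22 excluded), 18 empty individuals dropped
#>    mean 1 - WIC/TNW = 0.363; 6/14 tanks with significant IS
#>    significant ANOVA terms on the index: competition
#> == habitat: 35 tanks retained (1 excluded), 0 empty individuals dropped
#>    mean 1 - WIC/TNW = 0.226; 27/35 tanks with significant IS
#>    significant ANOVA terms on the index: predation

res$diet$anova$is_index
#>                    term ss_type df          SS          F            p partial_eta_sq
#> 1           competition      II  1 0.308011464 26.5348359 0.0004306963     0.72628863
#> 2             predation      II  1 0.001822511  0.1570072 0.7002500761     0.01545802
#> 3 competition:predation     III  1 0.004025194  0.3467659 0.5690119166     0.03351442
#> 4              residual         10 0.116078149         NA           NA             NA
```

Here the generator's competition effect (a benthic diet shift plus a
four-fold increase in kappa) is recovered as a strong competition main
effect on dietary IS (F = 26.5, partial eta squared = 0.73) with no
predation or interaction signal — the same shape of result the analysis is
designed to detect in real mesocosm data. `run_full_analysis(...,
out_dir = "report")` additionally writes tidy CSV tables, a JSON exclusion
log and a JSON manifest of seeds and settings.

To re-analyse the original deposited data set, fetch the deposit yourself
and point `replicate_paper()` at it with a column-mapping config; it runs
the same pipeline and tabulates each headline quantity against its
published value.

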