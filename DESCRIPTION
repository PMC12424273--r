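Package: nichevar
Title: Individual Specialisation Analysis for Replicated Mesocosm Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify individual specialisation (IS) in replicated
    experimental populations from repeated-measures resource-use data such as
    serial gastric-lavage stomach samples or focal habitat scans. Implements
    the Shannon-entropy partition of total niche width (TNW) into within- and
    between-individual components (WIC, BIC), the specialisation index
    1 - WIC/TNW, and a Monte Carlo stochastic-generalist null model for
    per-population significance. Population-level composition shifts are
    tested with Bray-Curtis dissimilarity, two-way PERMANOVA, homogeneity of
    multivariate dispersion, SIMPER taxon contributions and NMDS ordination,
    and per-population niche components are analysed with 2x2 factorial
    ANOVA (Type III/II sums of squares), partial eta squared effect sizes and
    Tukey HSD post-hoc comparisons. A Dirichlet-multinomial generator
    simulates complete factorial mesocosm experiments with controllable
    individual preference heterogeneity, treatment effects, sampling effort,
    empty stomachs and mortality-driven attrition, so that every stage of the
    analysis can be validated on data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    permute
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
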