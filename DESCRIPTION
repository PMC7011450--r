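Package: clonalGxE
Title: Multi-Environment Quantitative Genetics of Clonal Forestry Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative-genetic analysis of multi-site clonal
    (common-garden) trials, motivated by coast redwood provenance trials grown
    outside the species' natural range. Provides a synthetic trial-data
    generator with hierarchical population/genotype/replicate/block effects and
    cross-site genetic correlations; monthly-to-annual climate summaries and a
    collinearity screen; partitioning-around-medoids clustering of origin
    locations with silhouette-based selection of the number of clusters; a
    Gibbs-sampled multivariate mixed model treating each planting site as a
    dimension, yielding posterior modes and highest-posterior-density intervals
    for broad-sense heritabilities at population and genotype level and
    between-site genetic correlations (genotype-by-environment interaction);
    genotype rank-change diagnostics across sites; and a universal response
    function regressing productivity on climate at origin and at planting site
    with prediction over a climate grid, including extrapolation flags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
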