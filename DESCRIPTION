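Package: morphodiv
Title: Geometric Morphometrics and Molecular Divergence Pipelines for
    Island Isopod Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two complementary analyses of lineage
    diversification in supralittoral isopods. A landmark-based
    geometric-morphometric pipeline takes raw 27-landmark
    configurations through bilateral symmetrization, generalized
    Procrustes superimposition, tangent-space principal components,
    Type III MANCOVA with Wilks' lambda, Rao's F approximation and
    partial eta-squared, quadratic discriminant analysis with
    leave-one-out cross-validation, and thin-plate-spline shape
    visualization. A molecular-divergence pipeline computes
    Kimura-2-parameter distance summaries under exclusion masks and
    builds statistical-parsimony haplotype networks with inferred
    intermediate alleles. A synthetic-data module generates landmark
    datasets and haplotype sets with known structure so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    MASS,
    car,
    vegan,
    jsonlite
Config/testthat/edition: 3
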