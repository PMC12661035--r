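Package: cultureval
Title: Quantitative Evaluation of Laser-Assisted Culturomics Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to score how well cultured colony arrays recover the
    community composition of their inoculum from amplicon feature tables:
    taxonomy-aware profile handling and rarefaction, a PRIMER-style
    alpha-diversity suite (Hill numbers, Hurlbert rarefaction, Good's
    coverage), recovery and enrichment statistics with Mann-Whitney class
    shift tests, Bray-Curtis/UPGMA/non-metric MDS beta-diversity, greedy
    media-panel complementarity ranking with UpSet intersection counts,
    and FT-IR spectral preprocessing (baseline correction and vector
    normalization) with Fisher linear discriminant classification under
    cross-validation. A synthetic-community and synthetic-spectrum
    generator with known ground truth makes every stage testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
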