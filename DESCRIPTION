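Package: microhi
Title: Microbiota Health Index Pipeline for Host and Environmental Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the microbiota health index (microHI) from
    taxon-by-sample relative-abundance tables and a taxon-to-phenotype
    annotation map covering three health-negative phenotypes (potentially
    pathogenic, contains mobile elements, stress tolerant). Labels gut
    samples as having normal or disordered microbiota from their position
    in a Bray-Curtis / average-linkage dendrogram, relates gut microHI to
    water environmental microHI at community, population and ecotype
    levels, and screens for key health-impacting taxa with a correlation
    plus Kruskal-Wallis/LDA differential-abundance cascade. Ships a
    synthetic cohort generator with known ground truth so every stage of
    the pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vegan,
    MASS,
    ape
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
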