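Package: cocQuant
Title: Quantitative Imaging and Statistical Endpoints for Bovine In Vitro
    Oocyte Maturation Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image quantification and statistical analysis of the endpoints
    used in bovine in vitro oocyte maturation and embryo production screens
    for reproductive toxicity: oocyte mitochondrial distribution expressed
    as the relative peripheral fluorescence intensity (cortex versus center),
    cumulus-oocyte complex (COC) expansion measured as the fold-increase of
    projected surface area, TUNEL/ethidium-homodimer/Hoechst cytometry of
    cumulus cell nuclei with apoptotic and necrotic rate derivation, and the
    contingency and group-comparison statistics applied to nuclear
    maturation, cleavage, blastocyst and steroid endpoints (chi-square with
    Bonferroni-corrected post hoc z-tests, one-way ANOVA with Tukey HSD,
    Kruskal-Wallis with Dunn pairwise comparisons). A seeded synthetic
    fluorescence-scene and outcome-table generator with known ground truth
    allows every stage to be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-internal.R'
    'scene.R'
    'synthgen.R'
    'mito.R'
    'expansion.R'
    'cytometry.R'
    'stats.R'
    'io.R'
    'pipeline.R'
    'cocQuant-package.R'
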