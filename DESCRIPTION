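Package: paddyMeHg
Title: Gene-Centric Functional-Guild Quantification and Attribution of
    Methylmercury Variability in Paddy Soil Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for gene-centric quantification of mercury- and
    methane-cycling microbial guilds in soil metagenomes and for statistical
    attribution of methylmercury (MeHg) variability to those guilds and to
    soil geochemistry. Validates candidate marker-gene hits (hgcAB cap-helix
    and ferredoxin motifs, MerB residue signatures, BLAST-title keywords,
    taxon allow-lists, methanobactin cluster typing), normalizes per-ORF
    coverages to effective library sizes and HMM lengths, and provides the
    downstream inference machinery: AICc multiple-regression model selection,
    Bray-Curtis ordination with PERMANOVA and distance-based RDA, a repeated
    train/test random-forest permutation-importance protocol with per-split
    significance rates, and delay-aware local similarity analysis for short
    time series. A seeded synthetic-data generator emulates the field-study
    design (3 sites x 2 compartments x 11 time points) with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    edgeR,
    vegan,
    randomForest,
    lmtest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
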