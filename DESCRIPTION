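Package: adriboquant
Title: Quantitative TMT Proteomics of Intracellular ADP-Ribosylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed (TMT) chemical-proteomics
    experiments profiling intracellular ADP-ribosylation with clickable
    adenosine analogues. Parses MaxQuant proteinGroups tables and applies
    protein-level quality filters, normalises corrected reporter-ion
    intensities with the trimmed mean of M-values (TMM) method followed by
    a log2-per-million transformation, encodes two experiment designs as
    linear models (cofactor preference between 2YnAd and 6YnAd across a
    concentration series, and PARP-inhibitor response contrasting Olaparib
    and Rucaparib against vehicle control), fits per-protein least-squares
    models, and performs hierarchical empirical-Bayes moderated t-tests
    with an intensity-dependent variance prior and Benjamini-Hochberg
    significance calls. Includes exact nuisance-coefficient debiasing for
    plot-ready exports (volcano, inhibitor-response scatter, dose-response
    profiles) and a synthetic proteinGroups generator with ground truth
    for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    edgeR,
    yaml,
    optparse
Config/testthat/edition: 3
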