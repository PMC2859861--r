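Package: sshray
Title: Quantitative Screening of Suppression Subtractive Hybridization
    Libraries on Two-Colour Microarrays
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens suppression subtractive hybridization (SSH) cDNA
    libraries spotted on two-colour microarrays. Reads GenePix results
    (GPR), array list (GAL), targets and spot-type files; applies
    signal-to-noise spot weighting, normexp background correction,
    spike-in control-spot print-tip loess normalization within arrays and
    Aquantile normalization between arrays; fits per-clone dye-swap
    linear models with empirical-Bayes moderated t-statistics and
    B-statistics to estimate enrichment ratios (ER3 and inverse ER2);
    classifies clones into up/down x rare/abundant quadrants and writes
    ranked top tables and enrichment-ratio plots. Also provides
    redundancy-aware clone-sequence management: vector/adaptor trimming,
    grouping of redundant partners by local-alignment E-values,
    representative selection and annotated exports. A synthetic-array
    generator produces complete experiments with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    limma,
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
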