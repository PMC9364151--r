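Package: secretoscore
Title: Calibrated Hit Calling for TMT Proximity-Labelling Secretome Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of quantitative TMT (tandem mass tag) proximity-labelling
    secretome experiments with a case/control channel design. Implements
    false-positive-rate calibration of TMT-ratio cutoffs from positive and
    negative control protein lists, the per-protein enrichment score (the
    number of pairwise case/control ratios passing their calibrated cutoffs),
    an empirical-Bayes moderated t-test path with Benjamini-Hochberg
    correction, secretome annotation summaries (secreted, signal-peptide and
    transmembrane-helix fractions, list overlaps, hypergeometric tissue-panel
    enrichment), and peptide-to-topology mapping for ectodomain-shedding
    inference, including in-silico tryptic digestion. A seeded synthetic-data
    generator emulates the statistical structure of such experiments for
    validation and power exploration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
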