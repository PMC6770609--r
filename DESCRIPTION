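Package: bcngdose
Title: Transcriptional Cis-Effects of Broad Copy-Number Gains in Tumour Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for gene-dosage transcriptional cis-effects of
    broad (arm-level) copy-number gains in cancer cohorts. Calls arm-level
    gains and losses from segmented copy-number profiles, classifies
    karyotypes and isochromosome patterns, builds selected and control tumour
    groups, runs trimmed-mean-of-M-values normalised negative-binomial
    differential expression over four contrasts, assigns a transcript
    taxonomy (variable, positive, negative and overexpressed transcripts),
    computes the normalized chromosomal distribution index (NCDI) of any
    transcript class, and scores signed hypergeometric enrichment or
    depletion against gene sets. Ships a synthetic-cohort generator with an
    explicit copy-number dosage model so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
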