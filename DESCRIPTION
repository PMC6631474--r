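Package: pccomp
Title: Fatty-Acid-Level Composition of Bulk Phosphatidylcholine Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing kit-style phosphatidylcholine (PC) sum
    measures using side-chain resolving lipidomics data. Parses lipid shorthand
    nomenclature (kit, species and fatty-acid dialects), computes sum formulas,
    monoisotopic masses and isobar mass deltas, enumerates all theoretically
    possible isobaric fatty-acid-level constituents of each PC sum, estimates
    quantitative compositions (constituent proportions with percentile
    intervals) from paired platform concentration tables, tests their variation
    and replication across cohorts, quantifies cross-platform concordance via
    through-origin regression and Bland-Altman statistics, and ships a
    machine-readable reference composition table for imputing fatty-acid-level
    PC concentrations from PC sums. Includes a synthetic paired-cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
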