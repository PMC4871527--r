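Package: neoburden
Title: Neoantigen Prediction, Long-Peptide Vaccine Design, and Tumor
    Neoantigen Burden Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline from an annotated somatic mutation table to
    per-sample predicted MHC class I neoantigen counts and the probability
    of harboring at least one authentic (naturally processed and presented)
    neoantigen. Covers expression- and class-based mutation filtering with a
    stage-by-stage audit, construction of mutant protein contexts for
    missense, in-frame indel, and frameshift variants, enumeration of 8-11mer
    class I candidate windows, design of ~29mer synthetic long vaccine
    peptides, a uniform interface over MHC-I affinity predictors (a seeded
    synthetic predictor plus parsers for external predictor tables),
    per-locus scaling of neoantigen counts, the binomial authenticity model
    P = 1 - (1 - a)^N, cohort-level burden summaries, and seeded synthetic
    cohort generators emulating intermediate- (ovarian high-grade serous)
    and high- (lung) mutation-burden tumors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
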