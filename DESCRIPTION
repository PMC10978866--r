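Package: satmut
Title: Saturation-Mutagenesis Screen Design, Simulation and Enrichment Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for pooled saturation-mutagenesis (deep mutational
    scanning) drug-resistance screens over a single open reading frame:
    enumeration of the designed codon-variant library (19 missense + 1
    nonsense substitutions per position), ground-truthed simulation of
    drug selection and shotgun sequencing, codon-level variant calling
    from aligned read pairs, log2-fold-change and z-score enrichment
    scoring with significance calling, and positional, domain-level and
    patient-catalog summaries of the results.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rsamtools,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
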