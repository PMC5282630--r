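Package: multibilou
Title: Multi-Label BILOU Encoding and Structured Sequence Labeling for
    Disorder Mention Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for recognizing disorder mentions in clinical-style text,
    including mentions that are discontiguous or mutually overlapping. The
    core is a 24-bit multi-label extension of the BILOU tagging scheme in
    which each of six channels carries one mention's Beginning/Inside/Last/
    Unit role, so up to six overlapping mentions per sentence can be encoded
    as one label per token and recovered exactly by bitwise extraction.
    Includes BIOHD and BIOHD1234 baseline encoders with representability
    auditing, token-level feature extraction with word-cluster features, an
    averaged cost-augmented structured sequence labeler with exact Viterbi
    inference, strict/left/right mention-level evaluation, corpus structure
    statistics, a deterministic synthetic-corpus generator, BRAT-dialect
    standoff and CoNLL-style readers/writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
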