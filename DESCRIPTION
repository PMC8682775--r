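Package: synev
Title: Synonymous Variant Effect Prediction from Observation Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores every possible synonymous single-nucleotide variant (sSNV)
    in a set of coding transcripts for putative functional effect using only
    observation status and sequence/annotation features, with no conservation
    signal and no disease labels. Implements exhaustive sSNV enumeration and
    frequency-based status classification, a panel of codon usage bias and
    codon autocorrelation measures (CAI, fracOpt, CUB, ICDI, SCUO, tAI, TPI,
    CAM, CF) and their mutant-minus-wild-type delta forms, a 35-slot variant
    feature pipeline, transcript-balanced positive-unlabeled learning to
    separate never-observed variants into not-seen and unobservable sets, a
    two-stage gradient-boosted classifier with median-score relabeling into
    effect and no-effect sets, cross-species codon variation statistics
    (CSV extraction, codon mutation fraction, divergence trends), constraint
    bin analysis, and a synthetic data generator that emulates the full input
    structure for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
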