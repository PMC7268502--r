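Package: cnvConsensus
Title: Consensus Copy-Number Calling from Heterogeneous Caller Outputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds consensus copy-number (CN) profiles from the outputs of
    heterogeneous CNV callers: a gap-free coverage (read-depth) caller
    reporting absolute copy numbers, a hybrid caller reporting log2 ratios
    against a matched sample or non-negative ratios against a null alignment,
    and a referee caller whose deletion/amplification classes are trusted but
    whose magnitudes are not. Caller outputs are harmonised onto one absolute
    CN scale (ploidy-anchored bias normalisation, log2-to-absolute
    conversion, equalizer correction of null-ratio distortion), the genome is
    re-segmented on the union of all callers' breakpoints, a documented rule
    table with referee arbitration decides each bin, and bins are merged into
    segments annotated with a squared-disagreement error score. Includes the
    gene-level evaluation metrics (MSE, MAE, mean log ratio error, residual
    variance, micro-averaged Matthews correlation coefficient) and a
    seedable generator of ground-truthed synthetic caller outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
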