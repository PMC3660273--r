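Package: ffpetconcord
Title: Concordance of Expression Profiles from Formalin-Fixed and Fresh-Frozen Tissue Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating gene-expression profiling workflows for
    formalin-fixed, paraffin-embedded tissue (FFPET) against matched
    fresh-frozen (FF) material on short-oligonucleotide arrays. Provides a
    synthetic matched-cohort generator with known ground truth (planted
    differential expression, probe-design flaws and kit-specific RNA
    degradation), in-silico probe re-annotation and probe-set revision
    against a reference transcriptome, RMA-style expression-index
    estimation (convolution background correction, quantile normalization,
    median-polish summarization), limit-of-blank present calls and related
    quality metrics, FF-versus-FFPET sensitivity/specificity concordance
    scoring, principal component analysis of samples, and a one-call
    pipeline that runs all stages from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
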