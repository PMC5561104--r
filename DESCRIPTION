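Package: cistromekit
Title: Integrative Construction and Annotation of Reference Cistromes from ChIP-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A start-to-end toolkit for integrating heterogeneous ChIP-seq
    peak sets and signal profiles around transcriptional-regulator binding
    sites. Builds majority-vote consensus cistromes from replicate, study and
    context level peak sets with a configurable severity threshold; calibrates
    that threshold against shuffled random backgrounds; normalizes binned ChIP
    signal with a median-of-ratios size-factor method; quantifies cofactor
    co-occupancy by per-site Pearson correlation of normalized profiles;
    classes binding sites by experimental-context co-occurrence; annotates
    overlap with independent feature sets under replicate-support rules; and
    measures chromatin-state overlap enrichment with Z-score conversion.
    Includes a synthetic-data generator with planted, recoverable structure
    and a command-line interface orchestrating the full workflow from a plan
    file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
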