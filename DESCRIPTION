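Package: ysrna
Title: Mutant-Pool Profiling and Cleavage-Rule Inference for Y RNA-Derived
    Small RNAs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing saturation-mutagenesis pools of a Y RNA.
    Enumerates randomized-window variant libraries of a reference Y RNA,
    simulates small RNA sequencing reads from transfected mutant pools under
    configurable cleavage rules, trims high-definition (HD) adapter reads,
    demultiplexes reads to variants by exact matching, infers cleavage sites
    and fragment size classes, detects missing or depleted variants with
    sequence logos, extracts secondary-structure features from dot-bracket
    annotations, and recovers the structure- and sequence-dependent rules of
    Y RNA fragment biogenesis (3' cleavage 2-3 nt above stem S3, a >= 1 nt
    internal loop requirement, and a 5' UGGGU sequence motif).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
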