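Package: clustersim
Title: Simulation of Gene Cluster Evolution with Gene Conversion, and
    Benchmarking of Conversion Detectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of a gene cluster along a three-species
    primate-like phylogeny (New World monkey, Old World monkey, human) under
    segmental duplications, deletions, and interlocus gene conversions,
    interleaved with HKY85 nucleotide substitutions and optional purifying
    selection on conserved elements.  The true orthologous and self
    (paralogous) alignments are tracked in exact coordinates through every
    event, so that true multiple alignments of each homologous set can be
    emitted for conversion-detection software, and predictions from any
    detector can be scored against the known conversion tracts with
    per-basepair and pair-level (existence) sensitivity and false discovery
    rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
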