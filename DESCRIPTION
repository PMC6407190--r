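Package: karyofuse
Title: Simulation and Inference of Telomere-Centric Karyotype Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying chromosome-number reduction in grasses under the
    telomere-centric model. Simulates chromosome evolution (nested chromosome
    fusions, end-end joinings, reciprocal translocations, inversions, satellite
    loss, whole-genome duplication and fractionation), detects collinear gene
    blocks by dynamic-programming anchor chaining with a gap-penalty scoring
    scheme, paints extant chromosomes by ancestral origin, infers fusion-event
    trajectories from the paint, and evaluates a combinatorial null model for
    the enrichment of fusions between homoeologous chromosomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    IRanges,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
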