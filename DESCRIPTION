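Package: thermaa
Title: Temperature-Associated Amino Acid Composition Bias in Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies thermal-adaptation signatures in protein sequence
    composition. Implements the ERK and CvP-bias amino-acid usage statistics,
    reciprocal-best-hit orthology with life-style and ubiquity filters,
    Felsenstein's phylogenetically independent contrasts with a seeded
    permutation null for the contrast correlation, GC-neutral and
    purine-neutral codon-matched controls for nucleotide-composition
    confounding, and a synthetic-data generator (Yule trees, Brownian-motion
    temperature traits, composition-tilted proteomes, GC3-controlled coding
    sequences) that exercises the whole pipeline without external genome data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    phytools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
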