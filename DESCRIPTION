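Package: rnaprofile
Title: Per-Base RNA Secondary-Structure Context Probabilities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact computation of the probability that each base of an RNA
    sequence lies in each of six secondary-structure contexts (stem, hairpin
    loop, bulge loop, internal loop, multibranch loop, exterior loop) under
    the Turner nearest-neighbour energy model with a maximal base-pair span,
    via a banded inside-outside algorithm over an unambiguous structure
    grammar. Includes an exact enumeration oracle for short sequences,
    CLIP-seq structural-specificity statistics (position-wise signed P scores
    of motif-anchored binding sites against unbound and dinucleotide-shuffled
    negatives), and synthetic-data generators for random sequences and
    motif-planting fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    optparse,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
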