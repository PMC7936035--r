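Package: mitoRearr
Title: Mitochondrial Gene Order Rearrangement Analysis for Notothenioid Fish
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the structural evolution of vertebrate
    mitochondrial genomes, motivated by the extensive gene-order
    rearrangements of Antarctic notothenioid fish. Provides a signed
    circular gene-order data model with canonical linearization, executable
    rearrangement operators (transposition, inversion, inverse
    transposition, tandem duplication/triplication with random loss,
    partial random loss), breadth-first parsimony inference of minimal
    event paths, Sankoff ancestral gene-order reconstruction on a fixed
    phylogeny with homoplasy detection, intergenic-spacer extraction and
    gene-remnant scanning by local alignment (STD-ISP versus GR-ISP
    classification with a translated-peptide check), strand compositional
    bias statistics (AT/GC skews, degenerate third-codon-position pools,
    strand-symmetry tests, full-reversal decision rule), pairwise Ka/Ks
    estimation by the Nei-Gojobori method, and a mitogenome simulator with
    planted rearrangement events, strand-asymmetric substitution and
    decaying pseudogene remnants that provides ground truth for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
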