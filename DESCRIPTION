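Package: lassokit
Title: Discovery and Mass-Spectrometric Characterization of Lasso Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the discovery and characterization of lasso peptides, a
    class of ribosomally synthesized and post-translationally modified peptides
    (RiPPs) whose N-terminal amine is bonded to the side-chain carboxylate of an
    Asp or Glu near the core N terminus, forming a threaded macrolactam.
    Provides exact monoisotopic mass arithmetic for linear and cyclized
    peptides; leader/core prediction for precursor peptides from the conserved
    leader motif; theoretical a/b/y fragment-ion tables with lasso-topology
    observability flags; localization of the ring-closing residue from
    deconvoluted MS/MS peak lists; homology-seeded mining of biosynthetic gene
    clusters from annotated genomes; precursor sequence-similarity networks for
    subfamily assignment; and seeded generators of synthetic genomes,
    precursors and spectra for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
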