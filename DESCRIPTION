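Package: sqgsuite
Title: Sequence, Network, Kinetic and Structural Analysis of
    NAD+-Dependent Sulfoquinovosidases
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for defining and characterising protein families of
    NAD+-dependent sulfoquinovosidases (SQases, glycoside hydrolase family
    GH188) and their genomic, kinetic, mass-spectrometric and structural
    context. Provides iterative profile (PSSM) homology search with
    Gumbel-calibrated E-values, exact pairwise alignment with an
    alignment-score (AS) metric for sequence similarity networks (SSNs),
    centrality-guided threshold selection and clustering, +/-10-ORF genome
    neighbourhood extraction with rule-based sulfoglycolytic/sulfolytic
    pathway classification, Michaelis-Menten and cofactor-activation
    kinetics fitting, deuterium-label position inference from tandem-MS
    fragment shift patterns, and coordinate-level geometry (distances,
    side-chain rotation, Kabsch superposition RMSD, Shrake-Rupley SASA and
    dimer interface area). A synthetic-data module generates sequence
    families, annotated genomes, rate data and toy structures so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    igraph,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml,
    xml2
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
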