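Package: phyloAmiR
Title: Phylogeny-Guided Design of Multi-Target Artificial MicroRNA Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs pooled libraries of artificial microRNAs (amiRNAs) that
    each silence several closely related members of a gene family. Gene
    trees guide candidate generation per internal node, candidates are
    scored by a nearest-neighbor RNA duplex hybridization-energy fraction
    relative to a perfect-match duplex, and a node-budgeted top-down
    selection with sequence-similarity rules picks a compact multi-target
    set. Selected guides are assembled in silico into a miRNA precursor
    backbone with functional-class adaptors, screened for Golden Gate
    (BsaI) restriction sites, and exported as orderable oligos with a
    guide-to-gene network. Includes amplicon-sequencing representation QC
    (coverage and skew of read counts) and a synthetic gene-family and
    read-pool simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    yaml,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, GeneTarget, Phylogenetics, QualityControl
RoxygenNote: 7.3.3
Collate: 
    'FamilyTree.R'
    'GeneSet.R'
    'RcppExports.R'
    'thermo.R'
    'config.R'
    'design.R'
    'assembly.R'
    'phyloAmiR-package.R'
    'qc.R'
    'simdata.R'
    'utils.R'
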