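Package: zwitterscan
Title: Enumeration and Frequency Estimation of Viral-Human Zwitter
    Epitope Candidates from Non-Spliced and Cis-Spliced Peptides
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to enumerate all non-spliced and proteasome-generated
    cis-spliced short peptides (9mers by default) from protein sequences,
    intersect viral and human peptide universes to identify "zwitter"
    peptides (sequences derivable identically from self and non-self
    antigens), filter candidates by predicted HLA class I binding affinity
    (IC50), weight self-antigen presentation by thymic epithelial cell
    gene expression, and propagate experimentally estimated proteasome
    hydrolysis and splicing frequencies through the analysis by repeated
    subsampling. Includes a synthetic-data module that generates proteomes
    with planted zwitter pairs of known category, expression tables,
    in-vitro digestion product tables and calibrated toy binding matrices,
    so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Proteomics, ImmunoOncology, SequenceMatching, Software
RoxygenNote: 7.3.3
Collate: 
    'zwitterscan-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'binding.R'
    'enumerate.R'
    'pcps.R'
    'weighting.R'
    'zwitter.R'
    'pipeline.R'
    'proteome-io.R'
    'synthetic.R'
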