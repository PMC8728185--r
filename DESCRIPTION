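Package: scopeqc
Title: Quality-Control and Annotation Toolkit for SCOPe Protein Domain Releases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for working with SCOPe (Structural Classification of
    Proteins - extended) release data: readers and writers for the parseable
    dir.* files including the structural-heterogeneity (dir.inc) and
    tandem-repeat (dir.rep) annotation formats, RAF (Rapid Access Format)
    SEQRES-to-ATOM residue maps in versions 0.02 and 0.03, a family-level
    structural-heterogeneity flagging algorithm based on kernel density
    estimation of domain lengths, detection and trimming of terminal cloning,
    expression and purification tags via SEQADV metadata and UniProt sequence
    comparison, an offline variant-to-structure residue mapping core with
    nearest-resolved-residue fallback, and a deterministic synthetic fixture
    generator producing cross-consistent releases with planted anomalies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
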